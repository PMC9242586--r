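---
title: "Ghost ancestry: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ghost ancestry: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghostancestry)
```

This vignette explains the science implemented by the package: the
models behind each estimator, the parameters that matter and why their
defaults are what they are, what the synthetic-data generators do and do
not emulate, and the numerical and design choices made where the
methodology left the design open.

## The ancestry-dosage model

Local-ancestry inference programs emit, per SNP per diploid individual,
an *allele dosage*: the expected number of haplotypes (0–2) derived from
a focal source population. Here the dosage is polarised once, package
wide, to count copies of **red wolf** ancestry: 0 is homozygous coyote,
2 homozygous red wolf. Dosages from replicate inference runs are
averaged elementwise (`average_dosage_runs()`); a cell missing in any
replicate stays missing — dosages are never imputed, and every
downstream statistic (ancestry proportions, switch counts) simply
excludes missing cells.

Classification uses the conventional fixed bands: dosage < 0.8 is
homozygous coyote, 0.8–1.8 is heterozygous ("joint"), > 1.8 is
homozygous red wolf. The band boundaries are *inclusive* for the
heterozygous state (0.8 and 1.8 both classify as joint); this choice is
pinned by tests because the band is asymmetric around the heterozygous
dosage of 1 and boundary cells do occur in averaged dosages.

**Blocks.** Maximal same-state runs along a chromosome become blocks. A
block spans from its first to its last SNP (1-based inclusive); we do
not extend block edges toward the midpoints between flanking SNPs, so a
single-SNP block has length 0 Mb. This is the conservative,
map-independent convention: block lengths are then slight underestimates
rather than depending on local SNP spacing. Missing-state SNPs are
transparent — a run continues across them — because a missing dosage is
an inference failure, not evidence of a state change.

## Dating the admixture pulse

Under a single pulse of admixture $T$ generations ago with founding red
wolf proportion $z$, followed by closed random mating, each haplotype
accumulates recombination junctions at rate $T$ per Morgan, and a
junction separates different ancestries with probability $2z(1-z)$. A
diploid genome of genetic length $L$ cM therefore shows an expected

$$B = 0.04 \, T \, L \, z(1-z)$$

ancestry-state switches. The package uses $L = 2085$ cM for the 38 canid
autosomes and $L = 111$ cM for the X, and inverts the equation for $T$
(`estimate_generations()`); the inversion is exact wherever defined and
tested to 1e-12 over a $T$–$z$–$L$ grid. Calendar years average a 4-year
and a 2-year canid generation time, i.e. years $= 3T$.

Three related conventions:

- **Switch distance.** Adjacent blocks of coyote and red wolf state
  count two switches (both haplotypes change), coyote–joint and
  joint–red wolf count one. This equals the minimal number of
  per-haplotype ancestry changes over all phasings consistent with the
  unphased state sequence — an equivalence the tests verify exhaustively
  for every state sequence up to length 8.
- **Which z.** The $z$ entering the equation is the dosage-based
  proportion (mean dosage / 2) for the matching compartment (autosomes
  or X), not a block-length fraction; one definition, used everywhere.
- **Undefined dates.** $z = 0$ or $z = 1$ makes the pulse date
  undefined (an unadmixed compartment): `timing_report()` flags such
  samples rather than dropping them, with a compatibility option to
  render the flag as 0.0, the convention used in some published
  per-sample tables for X chromosomes fixed for one ancestry.

Reduced-representation data inflate block sizes (fewer, clustered
markers), which biases dates toward the recent; no correction is
applied because none is established, and users should read dates as
lower bounds on age in sparse data.

## Private alleles and rarefaction

An allele is private to a population when it is observed there and in no
other population of the declared set; both alleles of a biallelic locus
are eligible, and missing genotypes are ignored per locus per
population. Because observed private-allele counts scale with sample
size, the package also reports the rarefied expectation at a
standardised sample of $g$ gene copies: with $N_j$ copies in population
$j$ of which $N_{ij}$ carry allele $i$, the subsample-absence
probability is $Q_{ij}(g) = \binom{N_j - N_{ij}}{g} / \binom{N_j}{g}$,
and the expected private count for $j$ is
$\sum_i (1 - Q_{ij}) \prod_{j' \ne j} Q_{ij'}$. Binomials are computed
in the log domain (stable for copy counts of at least $10^4$). The
default standardisation is $g = 100$ gene copies, the conventional
choice when the focal population is of moderate size. Gene-copy counts
are locus-specific; loci where any population has fewer than $g$ called
copies are skipped at that $g$ and the skipped count reported.

One property worth stating precisely: the rarefied expectation is
monotone non-decreasing in $g$ **only** for alleles genuinely absent
from the other populations (every $Q_{ij'} = 1$). An allele shared
between populations contributes $(1-Q_{ij})\prod Q_{ij'}$, which rises
and then decays to zero as $g$ grows, so population curves over mixed
allele pools can decline. The tests assert monotonicity in the
truly-private regime and verify the general computation against a
Monte-Carlo subsampling oracle.

## Genotype quality control

The chain mirrors the standard RADseq protocol: drop loci with more
than 90% missing data, then individuals with more than 20% missing data
(computed on retained loci); remove singletons and private doubletons
(two minor-allele copies carried by one individual — two heterozygotes
in different individuals are kept); require minor allele frequency of at
least 3% (boundary inclusive). The "statistically neutral and unlinked"
set additionally prunes 50-SNP windows advanced by 5 SNPs whenever a
retained pair exceeds squared genotype correlation 0.5, and drops loci
with a Hardy–Weinberg exact-test p below 0.001.

Decisions the external tools leave unstated, fixed here:

- The missingness/rare-allele stages iterate to a fixed point (each
  pass only shrinks the matrix), because a single pass is not stable
  under re-application — dropping loci changes individual missingness
  and vice versa. This makes `run_qc()` idempotent.
- LD pruning resolves violating pairs left-to-right and drops the
  lower-MAF locus (ties: the later one); correlations use mean-imputed
  missing genotypes. These choices make results deterministic; they are
  not guaranteed to match any particular external tool bit-for-bit.
- The HWE test is the two-sided exact test: conditioning on allele
  counts, it sums the probabilities of all heterozygote counts of the
  same parity no more probable than the observed one. Monomorphic loci
  return p = 1.

## The morphology models

Body weight (kg) is regressed on ancestry with eight a priori candidate
mixed models — fixed-effect structures {1}, {auto}, {X}, {auto+X},
{auto+sex}, {auto+age}, {auto+sex+age}, {X+sex} — each with a random
intercept for trapping region, fitted by maximum likelihood so that AIC
is comparable across fixed-effect structures. The candidate set is fixed
in advance (the source methodology names eight models without listing
them; this set spans the biologically sensible main-effect
combinations). Fixed effects are reported with Wald intervals using a
t quantile (df = n − p): at cohort sizes in the tens the normal-quantile
interval is measurably anti-conservative. A singular random-intercept
fit falls back to the fixed-intercept linear model with a warning rather
than reporting a degenerate variance.

## What the simulators emulate — and what they do not

`simulate_pulse_admixture()` implements exactly the model the dating
equation assumes: one pulse, then $T$ generations of random union of
gametes in an effectively infinite population, crossovers Poisson per
Morgan with uniform positions (no interference, uniform recombination
via a linear cM–bp map per chromosome), founder haplotypes iid
Bernoulli($z$). Defaults are the study conditions: 31 individuals,
$z = 0.38$, $T = 7$ ($\approx 21$ years), the canid karyotype, 25
SNPs/Mb ($\approx$ 59,000 markers genome-wide), dosage noise SD 0.1.

Deliberately **not** emulated: finite population size and drift,
continuous or multi-pulse migration, crossover interference,
recombination-map heterogeneity, sex-biased demography on the X, male X
hemizygosity, linkage between the genotype loci of the private-allele
generator, and the spatial clustering of reduced-representation
markers. Passing recovery tests therefore show the estimators are
correct *under their own assumptions*; on real data the dominant known
deviations (marker clustering, drift) bias dates recent-ward and shrink
diversity, and are discussed above rather than corrected.

Dosage noise is Gaussian, clipped to [0, 2]. Because the heterozygous
band is asymmetric around dosage 1 (its lower edge is only 0.2 away),
the state error rate at noise SD 0.15 is governed by the 0.2/σ tail —
about 9% one-sided for affected states, roughly 7% overall at
$z = 0.5$ — and the tests check the empirical rate against this exact
Gaussian computation.

## Problem sizes and numerical choices

The test and acceptance suites run at sizes chosen to make sampling
error small relative to the tolerances they assert: 200-genome cohorts
at the full karyotype (25 SNPs/Mb, noise 0) for switch-count and dating
recovery across $T \in \{5, 10\}$, $z \in \{0.38, 0.5\}$; 200
morphology replicates at n = 200 (and n = 24, the study's own size, for
coverage); $10^5$ Monte-Carlo resamples for the rarefaction oracle;
exhaustive enumeration for switch counting (sequences to length 8) and
the HWE test (all count triples to n = 20). Dosage bounds are enforced
with a 1e-6 read tolerance (values beyond it are rejected with their
location, never clamped); block coordinates are 1-based inclusive
internally and 0-based half-open in BED output, a bijective conversion.

## Known limitations

Single-pulse dating compresses continuous admixture into one date;
dates from sparse or clustered markers skew recent; X-chromosome
estimates ignore hemizygosity and sex-biased processes; the rarefaction
expectation treats loci as independent; and the bundled per-sample
tables carry one documented transcription correction (a timing entry
printed with a displaced decimal point, stored at the column's scale and
flagged in the fixture header).
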