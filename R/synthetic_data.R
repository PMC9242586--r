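#' Simulation configuration for pulse-admixed genomes
#'
#' Conditions for the tract simulator. Defaults mirror the study system:
#' a cohort of 31 diploids, founding red wolf proportion z = 0.38 (the
#' cohort's mean autosomal ancestry), 7 generations since the pulse
#' (about 21 years at the 3-year average generation time, the scale of
#' the cohort's timing estimates), the canid karyotype (autosomes
#' totalling 2085 cM, X 111 cM), marker density 25 SNPs/Mb (about 59,000
#' genome-wide, the scale of the study's SNP panel), and dosage noise SD
#' 0.1.
#'
#' @param n number of diploid individuals.
#' @param generations generations T since the admixture pulse.
#' @param z founding red wolf proportion in \[0, 1\].
#' @param karyotype chromosome lengths, see [canid_karyotype()].
#' @param snp_per_mb marker density for dosage output.
#' @param noise_sd Gaussian dosage noise standard deviation.
#' @param seed mandatory integer seed; all generators are
#'   seed-deterministic.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n = 31, generations = 7, z = 0.38,
                       karyotype = canid_karyotype(), snp_per_mb = 25,
                       noise_sd = 0.1, seed) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  stopifnot(n >= 1, generations >= 0, z >= 0, z <= 1, snp_per_mb > 0,
            noise_sd >= 0)
  structure(list(n = as.integer(n), generations = as.integer(generations),
                 z = z, karyotype = karyotype, snp_per_mb = snp_per_mb,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

# one meiosis applied to every lineage of a haplotype's ancestry mosaic.
# starts: segment start positions (cM, first = 0); lins: lineage id per
# segment. Each lineage is one parental meiosis: crossover count ~
# Poisson(len/100), positions uniform on (0, len); segments alternate
# between the two (fresh, independent) parents of that lineage.
recombine_once <- function(starts, lins, len) {
  u <- unique(lins)
  ks <- stats::rpois(length(u), len / 100)
  cuts <- lapply(ks, function(k) sort.int(stats::runif(k, 0, len)))
  firsts <- sample.int(2L, length(u), replace = TRUE)
  imap <- match(lins, u)
  ends <- c(starts[-1L], len)
  ns <- vector("list", length(starts))
  nl <- vector("list", length(starts))
  for (j in seq_along(starts)) {
    i <- imap[j]
    cj <- cuts[[i]]
    inside <- cj[cj > starts[j] & cj < ends[j]]
    ss <- c(starts[j], inside)
    par <- (findInterval(ss, cj) + firsts[i]) %% 2L
    ns[[j]] <- ss
    nl[[j]] <- 2L * (i - 1L) + par
  }
  starts <- unlist(ns)
  lins <- unlist(nl)
  # merge adjacent segments that landed on the same parental lineage
  if (length(lins) > 1L) {
    keep <- c(TRUE, lins[-1L] != lins[-length(lins)])
    starts <- starts[keep]
    lins <- lins[keep]
  }
  list(starts = starts, lins = lins)
}

# simulate one haplotype of one chromosome: T generations of recombination
# in an effectively infinite random-mating population, then founder
# ancestries drawn iid Bernoulli(z). Returns cM tract starts and per-tract
# ancestry (1 = red wolf, 0 = coyote), adjacent equal tracts merged.
sim_haplotype <- function(len_cM, generations, z) {
  starts <- 0
  lins <- 1L
  if (generations > 0) for (t in seq_len(generations)) {
    r <- recombine_once(starts, lins, len_cM)
    starts <- r$starts
    lins <- r$lins
  }
  u <- unique(lins)
  anc_u <- stats::rbinom(length(u), 1L, z)
  anc <- anc_u[match(lins, u)]
  if (length(anc) > 1L) {
    keep <- c(TRUE, anc[-1L] != anc[-length(anc)])
    starts <- starts[keep]
    anc <- anc[keep]
  }
  list(starts = starts, anc = anc)
}

#' Simulate a cohort of pulse-admixed diploid tract genomes
#'
#' Generation 0: each founder haplotype is wholly red wolf with
#' probability z, otherwise wholly coyote. Each later generation forms an
#' offspring haplotype by recombining two haplotypes drawn from
#' independent parents (random union in an effectively infinite
#' population), with crossover counts Poisson(chromosome cM / 100) and
#' uniform crossover positions. After T generations the cohort's tract
#' genomes are returned with exact cM breakpoints -- the ground truth the
#' rest of the pipeline is validated against.
#'
#' @param cfg a [sim_config()].
#' @return object of class `tract_cohort`: list with `genomes` (per
#'   individual, per chromosome, haplotypes `h1`/`h2` of tract `starts`
#'   in cM and `anc` 0/1), `karyotype`, and `cfg`.
#' @export
simulate_pulse_admixture <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  k <- cfg$karyotype
  genomes <- lapply(seq_len(cfg$n), function(i) {
    chroms <- lapply(seq_len(nrow(k)), function(ci) {
      list(h1 = sim_haplotype(k$length_cM[ci], cfg$generations, cfg$z),
           h2 = sim_haplotype(k$length_cM[ci], cfg$generations, cfg$z))
    })
    names(chroms) <- k$chrom
    chroms
  })
  names(genomes) <- sprintf("ind%03d", seq_len(cfg$n))
  structure(list(genomes = genomes, karyotype = k, cfg = cfg),
            class = "tract_cohort")
}

#' @export
print.tract_cohort <- function(x, ...) {
  cat("Pulse-admixture tract cohort:", length(x$genomes),
      "diploid genomes,", nrow(x$karyotype), "chromosomes\n")
  cat(sprintf("  T = %d generations, z = %.3f, seed = %d\n",
              x$cfg$generations, x$cfg$z, x$cfg$seed))
  invisible(x)
}

# diploid ancestry-dosage step function of one chromosome: union of the
# two haplotypes' breakpoints with per-segment dosage anc1 + anc2
diploid_steps <- function(chrom) {
  s <- sort(unique(c(chrom$h1$starts, chrom$h2$starts)))
  d <- chrom$h1$anc[findInterval(s, chrom$h1$starts)] +
    chrom$h2$anc[findInterval(s, chrom$h2$starts)]
  if (length(d) > 1L) {
    keep <- c(TRUE, d[-1L] != d[-length(d)])
    s <- s[keep]
    d <- d[keep]
  }
  list(starts = s, dosage = d)
}

#' True diploid switch counts of a tract cohort
#'
#' Counts, directly from the simulated tracts (no marker discretisation),
#' the diploid ancestry-state switches per individual: the summed absolute
#' change in diploid dosage (0/1/2) across tract junctions, per
#' chromosome.
#'
#' @param cohort a `tract_cohort`.
#' @param chroms chromosomes to include (default: autosomes).
#' @return named integer vector, one switch count per individual.
#' @export
tract_switch_count <- function(cohort,
                               chroms = autosomes(cohort$karyotype)) {
  vapply(cohort$genomes, function(g) {
    sum(vapply(chroms, function(cc) {
      st <- diploid_steps(g[[cc]])
      sum(abs(diff(st$dosage)))
    }, numeric(1)))
  }, numeric(1))
}

#' True genome-wide ancestry fraction of a tract cohort
#'
#' Tract-length-weighted (cM) red wolf fraction per individual over the
#' requested chromosomes.
#'
#' @inheritParams tract_switch_count
#' @return named numeric vector in \[0, 1\].
#' @export
tract_ancestry_fraction <- function(cohort,
                                    chroms = autosomes(cohort$karyotype)) {
  k <- cohort$karyotype
  lens <- stats::setNames(k$length_cM, k$chrom)
  vapply(cohort$genomes, function(g) {
    tot <- 0
    rw <- 0
    for (cc in chroms) {
      st <- diploid_steps(g[[cc]])
      seg <- diff(c(st$starts, lens[cc]))
      tot <- tot + 2 * lens[cc]
      rw <- rw + sum(seg * st$dosage)
    }
    rw / tot
  }, numeric(1))
}

#' Dosage matrix from tract genomes
#'
#' Reads each SNP's diploid red wolf dosage (0, 1 or 2) off the simulated
#' tracts, converting physical positions to cM through the karyotype's
#' linear per-chromosome map, then adds Gaussian noise clipped to
#' \[0, 2\] (mirroring the bounded semantics of inferred dosages).
#'
#' @param cohort a `tract_cohort`.
#' @param map `snp_map` whose chromosomes and positions lie within the
#'   cohort's karyotype.
#' @param noise_sd Gaussian noise SD (default from the cohort's config).
#' @param seed optional seed for the noise draw (default: config seed +
#'   1, so tracts and noise are independently reproducible).
#' @return dosage matrix, individuals x SNPs.
#' @export
tracts_to_dosage <- function(cohort, map, noise_sd = cohort$cfg$noise_sd,
                             seed = cohort$cfg$seed + 1L) {
  k <- cohort$karyotype
  ki <- match(map$chrom, k$chrom)
  if (anyNA(ki)) stop("SNP map chromosome not in cohort karyotype")
  if (any(map$pos > k$length_bp[ki]))
    stop("SNP position beyond chromosome end")
  snp_cM <- map$pos / k$length_bp[ki] * k$length_cM[ki]
  n <- length(cohort$genomes)
  D <- matrix(NA_real_, n, nrow(map),
              dimnames = list(names(cohort$genomes), NULL))
  for (i in seq_len(n)) {
    g <- cohort$genomes[[i]]
    for (cc in unique(map$chrom)) {
      j <- which(map$chrom == cc)
      h1 <- g[[cc]]$h1
      h2 <- g[[cc]]$h2
      D[i, j] <- h1$anc[findInterval(snp_cM[j], h1$starts)] +
        h2$anc[findInterval(snp_cM[j], h2$starts)]
    }
  }
  if (noise_sd > 0) {
    set.seed(seed)
    D <- D + stats::rnorm(length(D), 0, noise_sd)
    D[D < 0] <- 0
    D[D > 2] <- 2
  }
  D
}

#' Simulate multi-population biallelic genotypes with planned private
#' alleles
#'
#' Loci are either shared -- a common alternate-allele frequency across
#' all populations, drawn uniformly from `shared_freq` and rejected (and
#' redrawn) if either allele fails to be observed in some population, so
#' shared loci never create incidental private alleles -- or planned
#' private: the alternate allele segregates at a stated frequency in one
#' designated population and is absent elsewhere. Genotypes are binomial
#' draws per individual. The realised truth (whether each planned private
#' allele was actually observed) is recorded.
#'
#' @param pop_sizes named integer vector of individuals per population.
#' @param n_loci total locus count (planned private loci included).
#' @param private_plan data frame with columns `pop`, `n_loci`, `freq`:
#'   how many loci carry an allele private to each population and at what
#'   frequency. `NULL` for none.
#' @param shared_freq range of shared alternate-allele frequencies.
#' @param seed integer seed.
#' @return list: `G` (genotype matrix), `pops` (label per sample),
#'   `truth` (per planned private locus: `locus`, `pop`, `freq`,
#'   `realized`).
#' @export
simulate_population_genotypes <- function(pop_sizes, n_loci,
                                          private_plan = NULL,
                                          shared_freq = c(0.2, 0.8),
                                          seed) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  stopifnot(n_loci >= 1, all(pop_sizes >= 1), !is.null(names(pop_sizes)))
  if (!is.null(private_plan)) {
    stopifnot(all(c("pop", "n_loci", "freq") %in% names(private_plan)),
              all(private_plan$pop %in% names(pop_sizes)),
              all(private_plan$freq > 0), all(private_plan$freq <= 1),
              sum(private_plan$n_loci) <= n_loci)
  }
  set.seed(seed)
  pops <- rep(names(pop_sizes), pop_sizes)
  n <- length(pops)
  G <- matrix(0L, n, n_loci,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              sprintf("L%04d", seq_len(n_loci))))
  truth <- NULL
  locus <- 0L
  if (!is.null(private_plan)) {
    for (r in seq_len(nrow(private_plan))) {
      for (l in seq_len(private_plan$n_loci[r])) {
        locus <- locus + 1L
        in_pop <- pops == private_plan$pop[r]
        G[in_pop, locus] <- stats::rbinom(sum(in_pop), 2L,
                                          private_plan$freq[r])
        truth <- rbind(truth, data.frame(
          locus = colnames(G)[locus], pop = private_plan$pop[r],
          freq = private_plan$freq[r],
          realized = any(G[in_pop, locus] > 0),
          stringsAsFactors = FALSE))
      }
    }
  }
  while (locus < n_loci) {
    locus <- locus + 1L
    for (try in seq_len(100L)) {
      f <- stats::runif(1, shared_freq[1], shared_freq[2])
      g <- stats::rbinom(n, 2L, f)
      cnt <- rowsum(g, pops)[, 1]
      npop <- rowsum(rep(1L, n), pops)[, 1]
      if (all(cnt > 0) && all(cnt < 2 * npop)) break
      g <- NULL
    }
    if (is.null(g))
      stop("could not realise a shared locus; increase population sizes")
    G[, locus] <- g
  }
  list(G = G, pops = pops, truth = truth)
}

#' Simulate a morphology table from cohort ancestry
#'
#' Body weight (kg) is generated as
#' `intercept + b_auto * z_auto + b_sex * I(male) + region intercept +
#' Gaussian noise`, with sexes assigned 50/50, age classes sampled
#' uniformly, individuals spread over `n_regions` trapping regions, and
#' region intercepts drawn Normal(0, `region_sd`).
#'
#' @param z_auto autosomal ancestry per individual, in \[0, 1\].
#' @param z_x X-linked ancestry per individual; by default drawn
#'   independently of weight (a null covariate for the X candidate
#'   models) from a Beta distribution centred near the cohort-scale X
#'   ancestry mean.
#' @param betas named vector: `intercept`, `z_auto`, `sex_male` (kg).
#' @param noise_sd residual SD in kg.
#' @param region_sd SD of the region random intercepts (kg).
#' @param n_regions number of trapping regions.
#' @param seed integer seed.
#' @return metadata data frame: `id`, `region`, `sex`, `age_class`,
#'   `weight`, `z_auto`, `z_x`; generating effects in attribute
#'   `"truth"`.
#' @export
simulate_morphology <- function(z_auto, z_x = NULL,
                                betas = c(intercept = 12, z_auto = 7.42,
                                          sex_male = 2.1),
                                noise_sd = 2, region_sd = 1,
                                n_regions = 4, seed) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  stopifnot(all(z_auto >= 0), all(z_auto <= 1))
  set.seed(seed)
  n <- length(z_auto)
  if (is.null(z_x)) z_x <- stats::rbeta(n, 2.3, 1.4)
  region <- sample(sprintf("region%d", seq_len(n_regions)), n,
                   replace = TRUE)
  region_eff <- stats::setNames(stats::rnorm(n_regions, 0, region_sd),
                                sprintf("region%d", seq_len(n_regions)))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  age <- sample(c("pup", "juvenile", "adult"), n, replace = TRUE)
  weight <- betas["intercept"] + betas["z_auto"] * z_auto +
    betas["sex_male"] * (sex == "M") + region_eff[region] +
    stats::rnorm(n, 0, noise_sd)
  out <- data.frame(id = sprintf("ind%03d", seq_len(n)), region = region,
                    sex = sex, age_class = age, weight = unname(weight),
                    z_auto = z_auto, z_x = z_x,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(betas = betas, region_effects = region_eff,
                             noise_sd = noise_sd)
  out
}
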