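Package: ghostancestry
Title: Ghost Ancestry Blocks, Admixture Timing, and Private-Allele
    Diversity in Hybrid Canid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream population-genomic analysis of "ghost" ancestry --
    genetic variation from an extirpated source population persisting in an
    extant admixed population. Converts per-SNP local-ancestry allele
    dosages into three-state ancestry tracks, segments ancestry blocks,
    dates admixture pulses from diploid ancestry-switch counts, counts and
    rarefies population-private alleles, applies standard SNP quality
    control (missingness, minor-allele frequency, Hardy-Weinberg exact
    tests, sliding-window linkage pruning), and relates genomic ancestry to
    morphometrics through AIC-ranked mixed models. A pulse-admixture tract
    simulator with known ground truth generates every input the pipeline
    consumes, so each estimator is validated against the generative model
    it assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    lme4,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
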