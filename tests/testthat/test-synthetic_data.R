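small_karyotype <- function() {
  k <- data.frame(chrom = c("1", "2", "X"),
                  length_bp = c(100e6, 80e6, 60e6),
                  length_cM = c(110, 90, 55))
  class(k) <- c("karyotype", "data.frame")
  k
}

test_that("degenerate pulse parameters give degenerate tract genomes", {
  cfg0 <- sim_config(n = 3, generations = 0, z = 0.5,
                     karyotype = small_karyotype(), seed = 1)
  c0 <- simulate_pulse_admixture(cfg0)
  for (g in c0$genomes) for (ch in g) {
    expect_length(ch$h1$anc, 1)
    expect_length(ch$h2$anc, 1)
  }

  cfg1 <- sim_config(n = 3, generations = 8, z = 1,
                     karyotype = small_karyotype(), seed = 2)
  c1 <- simulate_pulse_admixture(cfg1)
  for (g in c1$genomes) for (ch in g) {
    expect_equal(unique(c(ch$h1$anc, ch$h2$anc)), 1L)
  }
  expect_equal(unname(tract_switch_count(c1, c("1", "2", "X"))),
               rep(0, 3))
})

test_that("generators are seed-deterministic", {
  cfg <- sim_config(n = 4, generations = 5, z = 0.4,
                    karyotype = small_karyotype(), snp_per_mb = 1,
                    seed = 9)
  a <- simulate_pulse_admixture(cfg)
  b <- simulate_pulse_admixture(cfg)
  expect_identical(a$genomes, b$genomes)
  map <- even_snp_map(small_karyotype(), 1)
  expect_identical(tracts_to_dosage(a, map), tracts_to_dosage(b, map))

  g1 <- simulate_population_genotypes(c(A = 5, B = 5), 20, seed = 3)
  g2 <- simulate_population_genotypes(c(A = 5, B = 5), 20, seed = 3)
  expect_identical(g1$G, g2$G)
})

test_that("cohort ancestry converges to the founding proportion", {
  cfg <- sim_config(n = 60, generations = 4, z = 0.3,
                    karyotype = small_karyotype(), seed = 13)
  cohort <- simulate_pulse_admixture(cfg)
  zbar <- mean(tract_ancestry_fraction(cohort, c("1", "2")))
  # ~2^4 founders per haplotype genome; binomial-scale tolerance
  expect_lt(abs(zbar - 0.3), 4 * sqrt(0.3 * 0.7 / (60 * 2 * 16)) + 0.02)
})

test_that("switch counts track the pulse-model expectation", {
  cfg <- sim_config(n = 150, generations = 6, z = 0.5,
                    karyotype = small_karyotype(), seed = 17)
  cohort <- simulate_pulse_admixture(cfg)
  B <- tract_switch_count(cohort, c("1", "2"))
  want <- expected_switches(6, 200, 0.5)  # autosomes total 200 cM
  se <- sd(B) / sqrt(length(B))
  expect_lt(abs(mean(B) - want), 3 * se)
})

test_that("noise-free dosages reproduce the true tract states at every SNP", {
  cfg <- sim_config(n = 5, generations = 6, z = 0.4,
                    karyotype = small_karyotype(), snp_per_mb = 2,
                    seed = 19)
  cohort <- simulate_pulse_admixture(cfg)
  map <- even_snp_map(small_karyotype(), 2)
  D <- tracts_to_dosage(cohort, map, noise_sd = 0)
  expect_true(all(D %in% c(0, 1, 2)))
  states <- classify_dosages(D)
  expect_identical(unname(states), unname(matrix(as.integer(D), nrow(D))))

  expect_error(tracts_to_dosage(cohort, snp_map("1", 200e6,
                                                karyotype = canid_karyotype()),
                                noise_sd = 0), "chromosome")
})

test_that("noise-induced state errors match the Gaussian tail computation", {
  cfg <- sim_config(n = 10, generations = 6, z = 0.5,
                    karyotype = small_karyotype(), snp_per_mb = 5,
                    seed = 23)
  cohort <- simulate_pulse_admixture(cfg)
  map <- even_snp_map(small_karyotype(), 5)
  clean <- tracts_to_dosage(cohort, map, noise_sd = 0)
  sd_n <- 0.15
  noisy <- tracts_to_dosage(cohort, map, noise_sd = sd_n)
  err <- mean(classify_dosages(noisy) != classify_dosages(clean))
  expect_gt(length(clean), 10000)
  # exact per-state misclassification probabilities: clipping keeps the
  # hom states inside [0, 2], so errors come from the 0.8 / 1.8 band
  # edges (0.2 from the het and red wolf dosages, 0.8 from coyote)
  p_state <- c(`0` = pnorm(-0.8 / sd_n),
               `1` = pnorm(-0.2 / sd_n) + pnorm(-0.8 / sd_n),
               `2` = pnorm(-0.2 / sd_n))
  frac <- table(factor(clean, levels = 0:2)) / length(clean)
  p_exp <- sum(p_state * as.numeric(frac))
  se <- sqrt(p_exp * (1 - p_exp) / length(clean))
  expect_lt(abs(err - p_exp), 4 * se)
  expect_lt(err, 0.10)
})

test_that("planned private alleles are realised and bookkept", {
  plan <- data.frame(pop = "A", n_loci = 7, freq = 0.3)
  sim <- simulate_population_genotypes(c(A = 10, B = 10, C = 10), 30,
                                       private_plan = plan, seed = 29)
  cnt <- private_allele_count(sim$G, sim$pops)
  expect_lte(cnt["A"], 7)
  expect_equal(unname(cnt["A"]), sum(sim$truth$realized))
  # shared loci create no incidental private alleles
  expect_equal(unname(cnt["B"]), 0L)
  expect_equal(unname(cnt["C"]), 0L)

  plan1 <- data.frame(pop = "B", n_loci = 4, freq = 1.0)
  sim1 <- simulate_population_genotypes(c(A = 6, B = 6), 10,
                                        private_plan = plan1, seed = 31)
  expect_true(all(sim1$truth$realized))
  expect_equal(unname(private_allele_count(sim1$G, sim1$pops)["B"]), 4L)
})

test_that("simulated weights have the generating slope on average", {
  set.seed(37)
  slopes <- replicate(400, {
    z <- rbeta(24, 1.9, 3.1)
    m <- simulate_morphology(z, noise_sd = 2, region_sd = 0,
                             seed = sample.int(1e6, 1))
    coef(lm(weight ~ z_auto + sex, data = m))["z_auto"]
  })
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 7.42), 3 * se)
})
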