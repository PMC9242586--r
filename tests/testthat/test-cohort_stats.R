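test_that("group summaries use the n-1 standard deviation", {
  cohort <- swla_cohort_table()
  s <- summarize_by_group(cohort$redwolf_mb, cohort$group)
  nw <- s[s$group == "Cameron-NW", ]
  expect_equal(nw$n, 8)
  expect_equal(nw$mean, 56.2375)
  expect_equal(round(nw$sd, 1), 49.4)
  # the n-denominator SD (46.2) must NOT match: pins the convention
  v <- cohort$redwolf_mb[cohort$group == "Cameron-NW"]
  expect_equal(round(sqrt(mean((v - mean(v))^2)), 1), 46.2)
  expect_false(isTRUE(all.equal(nw$sd, sqrt(mean((v - mean(v))^2)),
                                tolerance = 1e-3)))

  overall <- summarize_by_group(cohort$prop_auto,
                                rep("all", nrow(cohort)))
  expect_equal(round(overall$mean, 2), 0.38)

  one <- summarize_by_group(5, "g")
  expect_true(is.na(one$sd))
  expect_equal(one$mean, 5)
  expect_error(summarize_by_group(1:3, c("a", "b", NA)), "group")
})

test_that("summaries are invariant to row order", {
  set.seed(61)
  v <- runif(20)
  g <- sample(letters[1:3], 20, replace = TRUE)
  p <- sample.int(20)
  expect_equal(summarize_by_group(v, g), summarize_by_group(v[p], g[p]))
})

test_that("block-size ratios reproduce the regional contrasts", {
  s <- swla_regional_summary()
  expect_equal(round(s$block_ratio_nw, 1), 3.5)
  expect_equal(round(s$block_ratio_ne, 1), 1.6)
  expect_equal(group_ratio(list(mean = 3), list(mean = 3)), 1)
  expect_error(group_ratio(list(mean = 3), list(mean = 0)), "denominator")
})

test_that("Welch test matches the closed-form computation", {
  a <- c(19.8, 20.4, 19.6, 17.8, 18.5, 18.9, 18.3, 18.7)
  b <- c(28.2, 26.6, 20.1, 23.3, 25.2, 22.1, 17.7, 27.6, 20.6, 13.7)
  w <- welch_test(a, b)
  se2 <- var(a) / length(a) + var(b) / length(b)
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / length(a))^2 / (length(a) - 1) +
                        (var(b) / length(b))^2 / (length(b) - 1))
  expect_equal(w$t, t_hand, tolerance = 1e-12)
  expect_equal(w$df, df_hand, tolerance = 1e-12)
  expect_equal(w$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)

  set.seed(62)
  for (i in 1:100) {
    x <- rnorm(sample(3:20, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:20, 1), mean = runif(1, -1, 1))
    w <- welch_test(x, y)
    s2 <- var(x) / length(x) + var(y) / length(y)
    expect_equal(w$t, (mean(x) - mean(y)) / sqrt(s2), tolerance = 1e-10)
  }

  same <- c(1, 2, 3)
  w0 <- welch_test(same, same)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
})

test_that("parish ancestry contrast is of the published order", {
  cohort <- swla_cohort_table()
  cam <- cohort$prop_auto[cohort$parish == "Cameron"]
  oth <- cohort$prop_auto[cohort$parish %in%
                            c("Jefferson Davis", "Iberville",
                              "East Baton Rouge")]
  expect_length(cam, 22)
  expect_length(oth, 8)
  p <- welch_test(cam, oth)$p
  expect_lt(p, 2e-4)   # printed value 2e-5; variant unstated, one order
  expect_gt(p, 2e-6)
})

test_that("PC-ancestry correlations behave under signal, null, and permutation", {
  set.seed(63)
  n <- 40
  anc <- runif(n)
  # genotype matrix whose dominant axis is ancestry
  X <- outer(anc, rnorm(60)) + matrix(rnorm(n * 60, sd = 0.05), n)
  r <- pc_ancestry_correlation(X, anc)
  expect_gt(r$abs_r[1], 0.99)

  # ancestry independent of genotypes: weak correlation
  X0 <- matrix(rbinom(n * 100, 2, 0.4), n)
  r0 <- pc_ancestry_correlation(X0, runif(n))
  expect_lt(r0$abs_r[1], 0.5)

  # permuting labels centres the correlation at zero
  perm <- replicate(100, {
    pc_ancestry_correlation(X0, sample(anc))$r[1]
  })
  expect_lt(abs(mean(perm)), 0.1)

  expect_error(pc_ancestry_correlation(X, rep(1, n)), "constant")

  # per-group means are used when groups are supplied
  gr <- rep(c("a", "b"), each = n / 2)
  rg <- pc_ancestry_correlation(X, anc, groups = gr)
  expect_true(is.finite(rg$r[1]))
})

test_that("morphology model selection recovers generating structure", {
  set.seed(64)
  z <- rbeta(120, 1.9, 3.1)
  # strong ancestry + sex signal
  m <- simulate_morphology(z, seed = 71)
  fit <- suppressWarnings(fit_morphology_models(m))
  expect_true(fit$top %in% c("auto_sex", "auto_sex_age"))
  co <- fit$coefficients
  zrow <- co[co$term == "z_auto", ]
  expect_gt(zrow$lower, 0)

  # null data: ancestry interval covers zero
  m0 <- simulate_morphology(z, betas = c(intercept = 12, z_auto = 0,
                                         sex_male = 0),
                            region_sd = 0, seed = 72)
  fit0 <- suppressWarnings(fit_morphology_models(m0))
  cf <- fit0$fits$auto_sex
  est <- if (inherits(cf, "merMod")) lme4::fixef(cf) else coef(cf)
  se <- sqrt(diag(as.matrix(vcov(cf))))
  expect_true(est["z_auto"] - 1.96 * se["z_auto"] < 0 &&
                est["z_auto"] + 1.96 * se["z_auto"] > 0)

  # region intercept shifts produce positive random-effect variance
  mr <- simulate_morphology(z, betas = c(intercept = 12, z_auto = 0,
                                         sex_male = 0),
                            noise_sd = 0.5, region_sd = 4, seed = 73)
  fitr <- fit_morphology_models(mr)
  f_int <- fitr$fits$intercept
  expect_true(inherits(f_int, "merMod"))
  vc <- as.data.frame(lme4::VarCorr(f_int))
  expect_gt(vc$vcov[vc$grp == "region"], 0)
})

test_that("noise-free weights are exactly linear in ancestry", {
  z <- seq(0.1, 0.9, length.out = 24)
  m <- simulate_morphology(z, noise_sd = 0, region_sd = 0, seed = 74)
  co <- coef(lm(weight ~ z_auto + sex, data = m))
  expect_equal(unname(co["z_auto"]), 7.42, tolerance = 1e-10)
  expect_equal(unname(co["sexM"]), 2.1, tolerance = 1e-10)
})
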