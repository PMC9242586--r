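#' Group summary statistics
#'
#' Mean, sample standard deviation (n - 1 denominator), minimum and
#' maximum of a numeric per-sample quantity within groups. Rounding to a
#' reporting precision is applied only at the reporting layer, never
#' internally.
#'
#' @param values numeric vector.
#' @param groups group label per value.
#' @param digits optional rounding applied to the returned statistics
#'   (`NULL` = none).
#' @return data frame: `group`, `n`, `mean`, `sd`, `min`, `max`. Groups
#'   of size 1 have `NA` sd.
#' @export
summarize_by_group <- function(values, groups, digits = NULL) {
  if (length(values) != length(groups))
    stop("values and groups must have the same length")
  if (anyNA(groups)) stop("every value must be assigned a group")
  idx <- split(seq_along(values), groups)
  if (any(lengths(idx) == 0)) stop("empty group")
  out <- do.call(rbind, lapply(names(idx), function(gname) {
    v <- values[idx[[gname]]]
    data.frame(group = gname, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  }))
  if (!is.null(digits)) {
    num <- c("mean", "sd", "min", "max")
    out[num] <- lapply(out[num], round, digits = digits)
  }
  out
}

#' Ratio of group means
#'
#' @param summary_a,summary_b single-row results of
#'   [summarize_by_group()] (or any objects with a `mean` component).
#' @param digits reporting precision for the returned ratio (`NULL` =
#'   none).
#' @return ratio of means, `mean_a / mean_b`.
#' @export
group_ratio <- function(summary_a, summary_b, digits = NULL) {
  a <- summary_a$mean; b <- summary_b$mean
  stopifnot(length(a) == 1, length(b) == 1)
  if (b == 0) stop("zero denominator mean")
  r <- a / b
  if (is.null(digits)) r else round(r, digits)
}

#' Welch two-sample t test
#'
#' Unequal-variance two-sided t test with Welch-Satterthwaite degrees of
#' freedom (wraps [stats::t.test()]).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
welch_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    stop("degenerate variance in both groups")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Correlation between principal-component scores and ancestry
#'
#' Runs a PCA on a centred genotype or dosage matrix and reports the
#' Pearson correlation between each sample's score on the leading
#' components and an ancestry value -- either per sample, or the mean
#' ancestry of the sample's geographic group (the per-group convention
#' used when samples cluster by origin). PCA axis signs are arbitrary, so
#' the absolute correlation is reported alongside the signed one.
#'
#' @param X numeric matrix, samples in rows (genotypes or dosages);
#'   constant columns are dropped before the PCA.
#' @param ancestry ancestry value per sample.
#' @param groups optional group label per sample; when given, each
#'   sample's ancestry is replaced by its group mean before correlating.
#' @param n_pc number of leading components to report.
#' @return data frame: `pc`, `r`, `abs_r`, `var_explained`.
#' @export
pc_ancestry_correlation <- function(X, ancestry, groups = NULL,
                                    n_pc = 2) {
  stopifnot(nrow(X) >= 2, ncol(X) >= 2, length(ancestry) == nrow(X))
  if (!is.null(groups)) {
    gm <- tapply(ancestry, groups, mean)
    ancestry <- as.numeric(gm[as.character(groups)])
  }
  if (stats::sd(ancestry) == 0) stop("ancestry is constant")
  keep <- apply(X, 2, function(col) stats::sd(col, na.rm = TRUE) > 0)
  Xk <- X[, keep, drop = FALSE]
  # mean-impute missing cells so prcomp can run on incomplete matrices
  if (anyNA(Xk))
    Xk <- apply(Xk, 2, function(col) {
      col[is.na(col)] <- mean(col, na.rm = TRUE); col
    })
  pca <- stats::prcomp(Xk, center = TRUE, scale. = FALSE)
  n_pc <- min(n_pc, ncol(pca$x))
  varex <- pca$sdev^2 / sum(pca$sdev^2)
  out <- do.call(rbind, lapply(seq_len(n_pc), function(k) {
    score <- pca$x[, k]
    if (stats::sd(score) == 0) stop("constant principal component ", k)
    r <- stats::cor(score, ancestry)
    data.frame(pc = k, r = r, abs_r = abs(r), var_explained = varex[k])
  }))
  out
}

# the a priori candidate fixed-effect structures for weight models; the
# full candidate set is fixed in advance of any fit
MORPHOLOGY_MODELS <- list(
  intercept      = "1",
  auto           = "z_auto",
  x              = "z_x",
  auto_x         = "z_auto + z_x",
  auto_sex       = "z_auto + sex",
  auto_age       = "z_auto + age_class",
  auto_sex_age   = "z_auto + sex + age_class",
  x_sex          = "z_x + sex"
)

#' Fit and rank the morphology candidate models
#'
#' Fits eight a priori mixed models of body weight (kg) on red wolf
#' ancestry: fixed-effect structures over autosomal ancestry, X-linked
#' ancestry, sex and age class, each with a random intercept for the
#' trapping region, fitted by maximum likelihood (so AIC is comparable
#' across fixed-effect structures) via \pkg{lme4}. Models are ranked by
#' AIC; fixed effects are reported with Wald standard errors and 95%
#' confidence intervals, a variable being called significant when its
#' interval excludes zero. A singular random-intercept fit falls back to
#' the fixed-intercept linear model with a warning.
#'
#' @param data data frame with columns `weight`, `z_auto`, `z_x`, `sex`,
#'   `age_class`, `region`.
#' @return object of class `morphology_fit`: `table` (model, AIC,
#'   delta-AIC rank), `top` (name of the AIC-best model), `coefficients`
#'   (fixed effects of the top model with `estimate`, `se`, `lower`,
#'   `upper`), `fits` (the fitted model objects).
#' @export
fit_morphology_models <- function(data) {
  req <- c("weight", "z_auto", "z_x", "sex", "age_class", "region")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  data <- data[stats::complete.cases(data[req]), , drop = FALSE]
  if (nrow(data) < 10) stop("need at least 10 complete cases")
  fits <- lapply(MORPHOLOGY_MODELS, function(rhs) {
    f <- stats::as.formula(paste("weight ~", rhs, "+ (1 | region)"))
    fit <- tryCatch(
      suppressMessages(lme4::lmer(f, data = data, REML = FALSE)),
      error = function(cond) NULL)
    if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5)) {
      warning("singular random-intercept fit for '", rhs,
              "'; falling back to fixed-intercept model", call. = FALSE)
      fit <- stats::lm(stats::as.formula(paste("weight ~", rhs)),
                       data = data)
    }
    fit
  })
  aic <- vapply(fits, stats::AIC, numeric(1))
  ord <- order(aic)
  tab <- data.frame(model = names(MORPHOLOGY_MODELS)[ord],
                    formula = unlist(MORPHOLOGY_MODELS)[ord],
                    AIC = aic[ord], delta_AIC = aic[ord] - min(aic),
                    row.names = NULL, stringsAsFactors = FALSE)
  top <- tab$model[1]
  coefs <- fixed_effect_table(fits[[top]])
  structure(list(table = tab, top = top, coefficients = coefs,
                 fits = fits, n = nrow(data)),
            class = "morphology_fit")
}

# Wald fixed-effect table (estimate, se, 95% CI) for lmer or lm fits.
# Intervals use a t quantile with df = n - p rather than the normal
# quantile: at cohort sizes in the tens the normal-quantile interval is
# anti-conservative.
fixed_effect_table <- function(fit) {
  if (inherits(fit, "merMod")) {
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    nobs <- lme4::getME(fit, "n")
  } else {
    est <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    nobs <- length(stats::resid(fit))
  }
  zc <- stats::qt(0.975, df = max(1, nobs - length(est)))
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             lower = unname(est - zc * se), upper = unname(est + zc * se),
             significant = unname(est - zc * se > 0 | est + zc * se < 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.morphology_fit <- function(x, ...) {
  cat("Morphology model selection (", x$n, " coyotes, ",
      nrow(x$table), " candidate mixed models)\n", sep = "")
  print.data.frame(x$table, digits = 4, row.names = FALSE)
  cat("\nTop model ('", x$top, "') fixed effects:\n", sep = "")
  print.data.frame(x$coefficients, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Regional summaries of the bundled cohort tables
#'
#' Recomputes, from the bundled per-sample ancestry/timing and block-size
#' tables alone, the derived regional quantities a reader would check
#' against the published summaries: cohort-wide and regional ancestry
#' means, regional timing means, per-state block-size summaries by
#' geographic subregion, and the red wolf/coyote block-size ratios.
#'
#' @return named list of data frames and numbers; see examples.
#' @export
#' @examples
#' s <- swla_regional_summary()
#' s$overall          # cohort-wide ancestry means
#' s$block_ratio_nw   # NW Cameron red wolf : coyote block-size ratio
swla_regional_summary <- function() {
  cohort <- swla_cohort_table()
  overall <- data.frame(
    n = nrow(cohort),
    prop_auto_mean = mean(cohort$prop_auto),
    prop_auto_sd = stats::sd(cohort$prop_auto),
    prop_x_mean = mean(cohort$prop_x),
    prop_x_sd = stats::sd(cohort$prop_x))
  cameron <- cohort[cohort$parish == "Cameron", ]
  # "other parishes" excludes Calcasieu's single coyote, matching the
  # three-parish grouping (Jefferson Davis, Iberville, East Baton Rouge)
  others <- cohort[cohort$parish %in%
                     c("Jefferson Davis", "Iberville",
                       "East Baton Rouge"), ]
  noncameron <- data.frame(
    n = nrow(others),
    prop_auto_mean = mean(others$prop_auto),
    prop_x_mean = mean(others$prop_x),
    timing_auto_mean = mean(others$timing_auto_years),
    timing_x_mean = mean(others$timing_x_years))
  cameron_summary <- data.frame(
    n = nrow(cameron),
    prop_auto_mean = mean(cameron$prop_auto),
    prop_x_mean = mean(cameron$prop_x),
    timing_auto_mean = mean(cameron$timing_auto_years),
    timing_x_mean = mean(cameron$timing_x_years))
  by_group <- function(col)
    summarize_by_group(cohort[[col]], cohort$group)
  pick <- function(df, grp) df[df$group == grp, , drop = FALSE]
  rw <- by_group("redwolf_mb")
  coy <- by_group("coyote_mb")
  list(overall = overall,
       cameron = cameron_summary,
       noncameron = noncameron,
       welch_auto = welch_test(cameron$prop_auto, others$prop_auto),
       welch_x = welch_test(cameron$prop_x, others$prop_x),
       ancestry_by_group = by_group("prop_auto"),
       timing_by_group = by_group("timing_auto_years"),
       redwolf_blocks_by_group = rw,
       coyote_blocks_by_group = coy,
       joint_blocks_by_group = by_group("joint_mb"),
       block_ratio_nw = group_ratio(pick(rw, "Cameron-NW"),
                                    pick(coy, "Cameron-NW")),
       block_ratio_ne = group_ratio(pick(rw, "Cameron-NE"),
                                    pick(coy, "Cameron-NE")))
}
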