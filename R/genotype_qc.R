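#' QC configuration
#'
#' Thresholds for the SNP/sample filtering chain. Defaults reproduce a
#' standard RADseq filtering protocol: drop loci with more than 90%
#' missing data, then individuals with more than 20% missing data, remove
#' singleton and private-doubleton alleles, require minor allele frequency
#' of at least 3%, and (for the "statistically neutral and unlinked" set)
#' prune 50-SNP windows advanced by 5 SNPs at a squared genotype
#' correlation of 0.5 and drop loci deviating from Hardy-Weinberg
#' equilibrium at an exact-test p below 0.001.
#'
#' @param max_locus_missing maximum tolerated locus missingness fraction.
#' @param max_indiv_missing maximum tolerated individual missingness.
#' @param min_maf minimum minor allele frequency (inclusive).
#' @param ld_window,ld_step,ld_r2 sliding-window LD pruning parameters.
#' @param hwe_alpha HWE exact-test significance threshold.
#' @param drop_singletons drop singleton and private-doubleton alleles.
#' @return a list of class `qc_config`.
#' @export
qc_config <- function(max_locus_missing = 0.90, max_indiv_missing = 0.20,
                      min_maf = 0.03, ld_window = 50L, ld_step = 5L,
                      ld_r2 = 0.5, hwe_alpha = 0.001,
                      drop_singletons = TRUE) {
  stopifnot(max_locus_missing > 0, max_locus_missing <= 1,
            max_indiv_missing > 0, max_indiv_missing <= 1,
            min_maf > 0, min_maf <= 1,
            ld_window >= ld_step, ld_step >= 1, ld_r2 > 0, ld_r2 <= 1,
            hwe_alpha > 0, hwe_alpha <= 1)
  structure(list(max_locus_missing = max_locus_missing,
                 max_indiv_missing = max_indiv_missing,
                 min_maf = min_maf, ld_window = as.integer(ld_window),
                 ld_step = as.integer(ld_step), ld_r2 = ld_r2,
                 hwe_alpha = hwe_alpha, drop_singletons = drop_singletons),
            class = "qc_config")
}

#' Filter loci and individuals by missingness
#'
#' Loci whose missing fraction exceeds `max_locus_missing` are removed
#' first; individuals whose missing fraction, computed on the retained
#' loci, exceeds `max_indiv_missing` are removed second. Thresholds are
#' exclusive ("more than"), so a locus at exactly 90% missing survives.
#'
#' @param G genotype matrix (samples x loci, `NA` = missing).
#' @param cfg a [qc_config()].
#' @return the filtered matrix with a `report` attribute listing dropped
#'   loci and individuals.
#' @export
filter_missingness <- function(G, cfg = qc_config()) {
  if (!nrow(G) || !ncol(G)) stop("empty genotype matrix")
  loc_miss <- colMeans(is.na(G))
  keep_loc <- loc_miss <= cfg$max_locus_missing
  if (!any(keep_loc)) stop("all loci removed by missingness filter")
  G2 <- G[, keep_loc, drop = FALSE]
  ind_miss <- rowMeans(is.na(G2))
  keep_ind <- ind_miss <= cfg$max_indiv_missing
  if (!any(keep_ind)) stop("all individuals removed by missingness filter")
  out <- G2[keep_ind, , drop = FALSE]
  attr(out, "report") <- list(
    dropped_loci = colnames(G)[!keep_loc] %||% which(!keep_loc),
    locus_missingness = loc_miss,
    dropped_individuals = rownames(G)[!keep_ind] %||% which(!keep_ind),
    individual_missingness = ind_miss)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minor allele count and frequency per locus, ignoring missing cells
minor_allele_stats <- function(G) {
  called <- colSums(!is.na(G))
  alt <- colSums(G, na.rm = TRUE)
  total <- 2 * called
  mac <- pmin(alt, total - alt)
  maf <- ifelse(total > 0, mac / total, NA_real_)
  list(mac = mac, maf = maf, alt = alt, total = total)
}

#' Remove rare alleles: singletons, private doubletons, and low MAF
#'
#' A locus is dropped when its minor allele is a singleton (one copy), or
#' a private doubleton (two copies both carried by a single individual,
#' i.e. one minor-allele homozygote and no other carrier); two
#' heterozygotes in different individuals are retained. Remaining loci
#' must have minor allele frequency of at least `min_maf` (inclusive
#' boundary: MAF exactly 3% survives the default).
#'
#' @inheritParams filter_missingness
#' @return filtered matrix with a `report` attribute.
#' @export
filter_rare <- function(G, cfg = qc_config()) {
  st <- minor_allele_stats(G)
  drop_sd <- rep(FALSE, ncol(G))
  if (cfg$drop_singletons) {
    minor_is_alt <- st$alt <= st$total - st$alt
    for (j in which(st$mac %in% c(1L, 2L))) {
      g <- G[, j]
      carriers <- if (minor_is_alt[j]) which(!is.na(g) & g > 0)
                  else which(!is.na(g) & g < 2)
      # singleton, or both copies in one individual
      if (st$mac[j] == 1L || length(carriers) == 1L) drop_sd[j] <- TRUE
    }
  }
  keep <- !drop_sd & !is.na(st$maf) & st$maf >= cfg$min_maf
  out <- G[, keep, drop = FALSE]
  if (!ncol(out)) warning("all loci removed by rare-allele filter")
  attr(out, "report") <- list(
    dropped_singleton = which(drop_sd),
    dropped_maf = which(!drop_sd & !(keep | is.na(st$maf))),
    maf = st$maf)
  out
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test from genotype counts: conditioning on the observed
#' allele counts, the p-value sums the probabilities of every heterozygote
#' count of the same parity whose probability does not exceed that of the
#' observed configuration. A monomorphic locus returns p = 1 by
#' convention. Computation is in the log domain and exact for any counts.
#'
#' @param nAA,nAa,naa non-negative integer genotype counts.
#' @return two-sided exact p-value.
#' @export
#' @examples
#' hwe_exact_test(5, 0, 5)   # strong heterozygote deficit
#' hwe_exact_test(1, 2, 1)   # modal configuration, p = 1
hwe_exact_test <- function(nAA, nAa, naa) {
  stopifnot(nAA >= 0, nAa >= 0, naa >= 0,
            nAA + nAa + naa >= 1,
            nAA == floor(nAA), nAa == floor(nAa), naa == floor(naa))
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1)
  hs <- seq.int(nA %% 2, min(nA, na), by = 2)
  logp <- lfactorial(n) - lfactorial((nA - hs) / 2) - lfactorial(hs) -
    lfactorial((na - hs) / 2) + hs * log(2) - lchoose(2 * n, nA)
  obs <- logp[match(nAa, hs)]
  sum(exp(logp[logp <= obs + 1e-9]))
}

#' HWE filter across a genotype matrix
#'
#' Applies [hwe_exact_test()] per locus and keeps loci with p >=
#' `hwe_alpha`.
#'
#' @inheritParams filter_missingness
#' @return filtered matrix with a `pvalues` attribute.
#' @export
filter_hwe <- function(G, cfg = qc_config()) {
  p <- vapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]
    g <- g[!is.na(g)]
    hwe_exact_test(sum(g == 2), sum(g == 1), sum(g == 0))
  }, numeric(1))
  out <- G[, p >= cfg$hwe_alpha, drop = FALSE]
  attr(out, "pvalues") <- p
  out
}

# squared genotype correlation on mean-imputed genotypes
geno_r2 <- function(x, y) {
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  y[is.na(y)] <- mean(y, na.rm = TRUE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)^2
}

#' Sliding-window LD pruning
#'
#' Greedy windowed pruning of correlated loci: within each window of
#' `ld_window` loci (ordered by map position), while any pair of retained
#' loci has squared genotype correlation above `ld_r2`, one of the pair is
#' dropped; the window then advances by `ld_step` loci. Correlations use
#' mean-imputed missing genotypes. The drop rule is deterministic: of a
#' violating pair, the locus with the lower minor allele frequency goes;
#' at equal MAF, the later locus goes. Violating pairs are resolved in
#' left-to-right order.
#'
#' @inheritParams filter_missingness
#' @return integer vector of retained locus indices (columns of `G`).
#' @export
ld_prune <- function(G, cfg = qc_config()) {
  L <- ncol(G)
  if (L < 2) return(seq_len(L))
  maf <- minor_allele_stats(G)$maf
  keep <- rep(TRUE, L)
  starts <- seq(1L, max(1L, L - 1L), by = cfg$ld_step)
  for (s in starts) {
    e <- min(L, s + cfg$ld_window - 1L)
    repeat {
      idx <- which(keep[s:e]) + s - 1L
      if (length(idx) < 2) break
      dropped <- FALSE
      for (a in seq_len(length(idx) - 1L)) {
        for (b in (a + 1L):length(idx)) {
          i <- idx[a]; j <- idx[b]
          if (geno_r2(G[, i], G[, j]) > cfg$ld_r2) {
            drop <- if (maf[i] < maf[j]) i
                    else if (maf[j] < maf[i]) j
                    else j
            keep[drop] <- FALSE
            dropped <- TRUE
            break
          }
        }
        if (dropped) break
      }
      if (!dropped) break
    }
    if (e == L) break
  }
  which(keep)
}

#' Run the full QC chain
#'
#' Applies, in order: missingness filtering (loci then individuals),
#' singleton/private-doubleton removal with the MAF floor, and -- when
#' `neutral = TRUE` -- sliding-window LD pruning and the HWE exact-test
#' filter, producing the "statistically neutral and unlinked" locus set,
#' a subset of the full set. The chain is idempotent: re-running it on its
#' own output changes nothing.
#'
#' @inheritParams filter_missingness
#' @param neutral also apply LD pruning and the HWE filter.
#' @return filtered genotype matrix; attribute `report` summarises each
#'   stage.
#' @export
run_qc <- function(G, cfg = qc_config(), neutral = FALSE) {
  # the missingness/rare-allele stages are iterated to a fixed point:
  # dropping loci changes individual missingness and dropping individuals
  # changes allele counts, so a single pass need not be stable under
  # re-application. Iteration only ever shrinks the matrix, so it
  # terminates, and makes the chain idempotent.
  g2 <- G
  rep_list <- list()
  repeat {
    dims <- dim(g2)
    g1 <- filter_missingness(g2, cfg)
    r1 <- attr(g1, "report")
    g2 <- filter_rare(g1, cfg)
    r2 <- attr(g2, "report")
    if (is.null(rep_list$missingness)) {
      rep_list <- list(missingness = r1, rare = r2)
    } else {
      rep_list$missingness$dropped_loci <-
        c(rep_list$missingness$dropped_loci, r1$dropped_loci)
      rep_list$missingness$dropped_individuals <-
        c(rep_list$missingness$dropped_individuals,
          r1$dropped_individuals)
    }
    if (identical(dim(g2), dims)) break
  }
  out <- g2
  if (neutral) {
    keep <- ld_prune(g2, cfg)
    g3 <- g2[, keep, drop = FALSE]
    rep_list$ld_retained <- keep
    out <- filter_hwe(g3, cfg)
    rep_list$hwe_pvalues <- attr(out, "pvalues")
  }
  attr(out, "report") <- rep_list
  out
}

#' Write a QC report as TSV
#'
#' One row per removed locus or individual with the removal reason.
#'
#' @param G filtered matrix from [run_qc()].
#' @param path output file.
#' @export
write_qc_report <- function(G, path) {
  r <- attr(G, "report")
  rows <- list()
  add <- function(item, reason)
    if (length(item)) data.frame(item = as.character(item), reason = reason)
  rows <- rbind(
    add(r$missingness$dropped_loci, "locus_missingness"),
    add(r$missingness$dropped_individuals, "individual_missingness"),
    add(r$rare$dropped_singleton, "singleton_or_private_doubleton"),
    add(r$rare$dropped_maf, "maf"))
  if (is.null(rows)) rows <- data.frame(item = character(), reason = character())
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
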