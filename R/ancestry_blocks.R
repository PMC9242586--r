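ANCESTRY_STATES <- c("coyote", "joint", "redwolf")

state_code <- function(state) {
  match(state, ANCESTRY_STATES) - 1L
}

#' Classify allele dosages into three ancestry states
#'
#' Dosage thresholds: below 0.8 is homozygous coyote, 0.8 to 1.8
#' (inclusive on both boundaries) is heterozygous ("joint"), above 1.8 is
#' homozygous red wolf. Missing dosages stay missing.
#'
#' @param D dosage matrix (samples x SNPs, values in \[0, 2\]).
#' @param het_low,het_high classification band boundaries.
#' @return integer state matrix: 0 = coyote, 1 = joint, 2 = red wolf,
#'   `NA` = missing; same dimnames as `D`.
#' @export
#' @examples
#' classify_dosages(matrix(c(0.5, 0.8, 1.8, 1.81), 1))
classify_dosages <- function(D, het_low = 0.8, het_high = 1.8) {
  s <- matrix(NA_integer_, nrow(D), ncol(D), dimnames = dimnames(D))
  s[!is.na(D) & D < het_low] <- 0L
  s[!is.na(D) & D >= het_low & D <= het_high] <- 1L
  s[!is.na(D) & D > het_high] <- 2L
  s
}

#' Segment state sequences into ancestry blocks
#'
#' Maximal runs of identical ancestry state along each chromosome become
#' blocks. A block spans from the first to the last SNP of its run
#' (1-based inclusive base pairs; no extension toward flanking SNPs), so a
#' single-SNP block has length 0 Mb. Missing-state SNPs are transparent:
#' runs continue across them.
#'
#' @param states integer state matrix from [classify_dosages()].
#' @param map `snp_map` aligned to the columns of `states`.
#' @return data frame with one row per block: `sample`, `chrom`, `start`,
#'   `end`, `state` (`"coyote"`, `"joint"`, `"redwolf"`), `n_snp`,
#'   `length_mb`.
#' @export
segment_blocks <- function(states, map) {
  if (ncol(states) != nrow(map))
    stop("state matrix and snp map disagree in SNP count")
  samples <- rownames(states) %||% as.character(seq_len(nrow(states)))
  chrom_levels <- unique(map$chrom)
  out <- vector("list", nrow(states) * length(chrom_levels))
  k <- 0L
  for (i in seq_len(nrow(states))) {
    for (cc in chrom_levels) {
      idx <- which(map$chrom == cc)
      s <- states[i, idx]
      pos <- map$pos[idx]
      ok <- !is.na(s)
      if (!any(ok)) next
      s <- s[ok]; pos <- pos[ok]
      r <- rle(s)
      ends_i <- cumsum(r$lengths)
      starts_i <- ends_i - r$lengths + 1L
      k <- k + 1L
      out[[k]] <- data.frame(
        sample = samples[i], chrom = cc,
        start = pos[starts_i], end = pos[ends_i],
        state = ANCESTRY_STATES[r$values + 1L],
        n_snp = r$lengths,
        length_mb = (pos[ends_i] - pos[starts_i]) / 1e6,
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      state = character(), n_snp = integer(),
                      length_mb = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out[seq_len(k)])
}

#' Genome-wide ancestry proportion from dosages
#'
#' The red wolf ancestry proportion z is the mean non-missing dosage over
#' the requested chromosomes divided by 2. Missing dosages are excluded,
#' not imputed.
#'
#' @param D dosage matrix (samples x SNPs).
#' @param map `snp_map` aligned to columns of `D`.
#' @param chroms chromosome ids to include (e.g. autosomes, or `"X"`).
#' @return named numeric vector of z per sample, in \[0, 1\].
#' @export
ancestry_proportion <- function(D, map, chroms) {
  idx <- which(map$chrom %in% chroms)
  if (!length(idx)) stop("no SNPs on the requested chromosomes")
  sub <- D[, idx, drop = FALSE]
  if (all(is.na(sub))) stop("no non-missing dosages on requested chromosomes")
  rowMeans(sub, na.rm = TRUE) / 2
}

#' Count diploid ancestry switches
#'
#' Sums, over adjacent block pairs within each chromosome, the state
#' distance: coyote-joint and joint-redwolf adjacencies count 1 switch,
#' coyote-redwolf counts 2 (both haplotypes must change). Chromosome ends
#' contribute no switches. This equals the minimal number of per-haplotype
#' ancestry changes over all phasings consistent with the unphased state
#' sequence.
#'
#' @param blocks block table from [segment_blocks()].
#' @param chroms chromosomes to include.
#' @param samples samples to include (default: all in `blocks`).
#' @return named integer vector of switch counts per sample.
#' @export
count_switches <- function(blocks, chroms = unique(blocks$chrom),
                           samples = unique(blocks$sample)) {
  b <- blocks[blocks$chrom %in% chroms & blocks$sample %in% samples, ,
              drop = FALSE]
  out <- stats::setNames(integer(length(samples)), samples)
  if (!nrow(b)) return(out)
  code <- state_code(b$state)
  key <- paste(b$sample, b$chrom, sep = "\r")
  for (grp in split(seq_len(nrow(b)), key)) {
    s <- b$sample[grp[1]]
    out[s] <- out[s] + sum(abs(diff(code[grp[order(b$start[grp])]])))
  }
  out
}

#' Per-sample, per-state block length statistics
#'
#' Mean and longest block length (Mb) for each ancestry state, autosomes
#' only (the conventional per-coyote block-size summary). States with no
#' blocks report 0 and are flagged absent.
#'
#' @param blocks block table from [segment_blocks()].
#' @param x_chrom chromosome id excluded as the X.
#' @return data frame: `sample`, `state`, `n_blocks`, `mean_mb`,
#'   `longest_mb`, `present`.
#' @export
block_statistics <- function(blocks, x_chrom = "X") {
  b <- blocks[!(blocks$chrom %in% x_chrom), , drop = FALSE]
  samples <- unique(blocks$sample)
  grid <- expand.grid(sample = samples, state = ANCESTRY_STATES,
                      stringsAsFactors = FALSE)
  stat <- function(s, st) {
    len <- b$length_mb[b$sample == s & b$state == st]
    if (!length(len)) return(c(0, 0, 0))
    c(length(len), mean(len), max(len))
  }
  vals <- t(mapply(stat, grid$sample, grid$state))
  data.frame(sample = grid$sample, state = grid$state,
             n_blocks = as.integer(vals[, 1]), mean_mb = vals[, 2],
             longest_mb = vals[, 3], present = vals[, 1] > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit an ancestry profile from a dosage matrix
#'
#' The central analysis of the package: classifies per-SNP red wolf allele
#' dosages into three ancestry states, segments ancestry blocks along each
#' chromosome, and derives per-sample summaries -- autosomal and X-linked
#' ancestry proportions z, diploid ancestry-switch counts B, block length
#' statistics, and admixture-timing estimates from the pulse model
#' B = 0.04 T L z (1 - z) with calendar years = 3 T (the mean of 2- and
#' 4-year canid generation times).
#'
#' @param D dosage matrix (samples x SNPs, red wolf allele dosage in
#'   \[0, 2\]).
#' @param map `snp_map` aligned to the columns of `D`.
#' @param x_chrom chromosome id of the X.
#' @param lengths genetic map lengths from [genome_lengths()].
#' @param het_low,het_high dosage classification band.
#' @return an object of class `ancestry_profile` with components
#'   `states`, `blocks`, `summary` (per-sample z/B/block statistics),
#'   `timing` (per-sample, per-compartment timing estimates), `map`, and
#'   `call`. Methods: `print`, `summary`, `plot`, `as.data.frame`.
#' @export
#' @examples
#' cfg <- sim_config(n = 4, generations = 6, z = 0.4, snp_per_mb = 2,
#'                   noise_sd = 0, seed = 1)
#' cohort <- simulate_pulse_admixture(cfg)
#' map <- even_snp_map(cfg$karyotype, per_mb = cfg$snp_per_mb)
#' D <- tracts_to_dosage(cohort, map, noise_sd = 0)
#' fit <- ancestry_profile(D, map)
#' fit
ancestry_profile <- function(D, map, x_chrom = "X",
                             lengths = genome_lengths(),
                             het_low = 0.8, het_high = 1.8) {
  D <- check_dosage(D, map)
  states <- classify_dosages(D, het_low, het_high)
  blocks <- segment_blocks(states, map)
  auto <- setdiff(unique(map$chrom), x_chrom)
  has_x <- x_chrom %in% map$chrom
  samples <- rownames(D) %||% as.character(seq_len(nrow(D)))
  z_auto <- ancestry_proportion(D, map, auto)
  B_auto <- count_switches(blocks, chroms = auto, samples = samples)
  summ <- data.frame(sample = samples, z_auto = unname(z_auto),
                     B_auto = unname(B_auto[samples]),
                     stringsAsFactors = FALSE)
  if (has_x) {
    summ$z_x <- unname(ancestry_proportion(D, map, x_chrom)[samples])
    summ$B_x <- unname(count_switches(blocks, chroms = x_chrom,
                                      samples = samples)[samples])
  }
  bs <- block_statistics(blocks, x_chrom = x_chrom)
  timing <- timing_report(summ, lengths = lengths)
  structure(list(states = states, blocks = blocks, summary = summ,
                 block_stats = bs, timing = timing, map = map,
                 x_chrom = x_chrom, call = match.call()),
            class = "ancestry_profile")
}

#' @export
print.ancestry_profile <- function(x, ...) {
  n <- nrow(x$summary)
  cat("Ancestry profile:", n, "sample(s),", nrow(x$map), "SNPs,",
      length(unique(x$map$chrom)), "chromosomes\n")
  cat(sprintf("  autosomal red wolf ancestry z: %.3f (range %.3f-%.3f)\n",
              mean(x$summary$z_auto), min(x$summary$z_auto),
              max(x$summary$z_auto)))
  if (!is.null(x$summary$z_x))
    cat(sprintf("  X-linked red wolf ancestry z:  %.3f\n",
                mean(x$summary$z_x)))
  ta <- x$timing$years[x$timing$compartment == "autosomal"]
  if (any(is.finite(ta)))
    cat(sprintf("  mean autosomal admixture age:  %.1f years\n",
                mean(ta[is.finite(ta)])))
  invisible(x)
}

#' @export
summary.ancestry_profile <- function(object, ...) {
  t_wide <- stats::reshape(
    object$timing[, c("sample", "compartment", "years")],
    direction = "wide", idvar = "sample", timevar = "compartment")
  out <- merge(object$summary, t_wide, by = "sample", sort = FALSE)
  names(out) <- sub("^years\\.", "timing_years_", names(out))
  class(out) <- c("summary.ancestry_profile", "data.frame")
  out
}

#' @export
print.summary.ancestry_profile <- function(x, digits = 3, ...) {
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.ancestry_profile <- function(x, ...) {
  as.data.frame(summary(x))
}

#' Chromosome ancestry painting
#'
#' Draws the ancestry blocks of one sample as coloured horizontal bars,
#' one per chromosome (grey = coyote, orange = joint, red = red wolf).
#'
#' @param x an `ancestry_profile`.
#' @param sample sample id to draw (default: first).
#' @param ... passed to [graphics::plot()].
#' @export
plot.ancestry_profile <- function(x, sample = x$summary$sample[1], ...) {
  b <- x$blocks[x$blocks$sample == sample, , drop = FALSE]
  if (!nrow(b)) stop("no blocks for sample ", sample)
  chroms <- unique(x$map$chrom)
  cols <- c(coyote = "grey70", joint = "darkorange", redwolf = "firebrick")
  graphics::plot(NA, xlim = c(0, max(b$end) / 1e6),
                 ylim = c(0, length(chroms) + 1), yaxt = "n",
                 xlab = "position (Mb)", ylab = "",
                 main = paste("Ancestry blocks:", sample), ...)
  graphics::axis(2, at = seq_along(chroms), labels = chroms, las = 2,
                 cex.axis = 0.6)
  for (i in seq_along(chroms)) {
    bb <- b[b$chrom == chroms[i], , drop = FALSE]
    if (!nrow(bb)) next
    graphics::rect(bb$start / 1e6, i - 0.35, bb$end / 1e6, i + 0.35,
                   col = cols[bb$state], border = NA)
  }
  invisible(x)
}
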