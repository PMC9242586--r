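# internal: per-population allele bookkeeping for biallelic loci.
# Returns, per population x locus: called genotype count, alternate and
# reference allele counts (missing genotypes ignored per locus).
pop_allele_counts <- function(G, pops) {
  if (length(pops) != nrow(G))
    stop("pops must label every sample (one label per row of G)")
  pops <- as.character(pops)
  if (length(unique(pops)) < 2)
    stop("need at least two populations")
  called <- rowsum(1L * !is.na(G), pops)
  altc <- rowsum(ifelse(is.na(G), 0L, G), pops)
  zero <- rowSums(called) == 0
  if (any(zero))
    stop("population with no called genotypes at any locus: ",
         rownames(called)[zero][1])
  list(called = called, alt = altc, ref = 2L * called - altc,
       pops = rownames(called))
}

#' Count population-private alleles
#'
#' For each population, counts (locus, allele) pairs where the allele is
#' present (count > 0) in that population and absent from every other
#' population, missing genotypes ignored per locus per population. Both
#' the reference and alternate allele of each biallelic locus are
#' eligible.
#'
#' @param G biallelic genotype matrix (samples x loci, alternate-allele
#'   counts, `NA` = missing).
#' @param pops population label per sample (vector aligned to rows of
#'   `G`).
#' @return named integer vector: private-allele count per population.
#' @export
private_allele_count <- function(G, pops) {
  ac <- pop_allele_counts(G, pops)
  count_private <- function(cnt) {
    pres <- cnt > 0
    npres <- colSums(pres)
    # private: present in exactly one population
    priv <- pres & rep(npres == 1, each = nrow(pres))
    rowSums(priv)
  }
  out <- count_private(ac$alt) + count_private(ac$ref)
  stats::setNames(as.integer(out), ac$pops)
}

#' Rarefaction-standardised private-allele richness
#'
#' ADZE-style combinatorial rarefaction: for allele i in population j with
#' N_j gene copies at a locus, of which N_ij carry the allele, the
#' probability that a random subsample of g copies contains no copy of
#' the allele is Q_ij(g) = C(N_j - N_ij, g) / C(N_j, g). The expected
#' number of alleles private to population j at standardised sample size
#' g is the sum over loci and alleles of
#' (1 - Q_ij(g)) * prod over other populations j' of Q_ij'(g).
#' Gene-copy counts are locus-specific (2 x called genotypes); loci where
#' any population has fewer than g copies are skipped at that g, with the
#' skipped count attached as attribute `"skipped"`. Binomial coefficients
#' are computed in the log domain, stable for copy counts up to at least
#' 1e4. At g equal to every population's full copy count the expectation
#' equals the observed private-allele count exactly.
#'
#' @inheritParams private_allele_count
#' @param g standardised sample size in gene copies (>= 2).
#' @return named numeric vector: expected private-allele count per
#'   population, with attribute `skipped` (loci skipped at this g).
#' @export
rarefied_private_alleles <- function(G, pops, g) {
  stopifnot(g >= 2, g == floor(g))
  ac <- pop_allele_counts(G, pops)
  max_copies <- 2 * rowsum(rep(1L, length(pops)), as.character(pops))[, 1]
  short <- max_copies < g
  if (any(short))
    stop("g = ", g, " exceeds the gene copies of population ",
         names(max_copies)[short][1])
  tot <- 2 * ac$called                       # pops x loci gene copies
  usable <- colSums(tot < g) == 0
  P <- length(ac$pops)
  out <- stats::setNames(numeric(P), ac$pops)
  if (any(usable)) {
    q_absent <- function(cnt) {
      # P x loci matrix of Q_ij(g), log-domain binomials
      n_without <- tot[, usable, drop = FALSE] - cnt[, usable, drop = FALSE]
      exp(lchoose(n_without, g) - lchoose(tot[, usable, drop = FALSE], g))
    }
    for (cnt in list(ac$alt, ac$ref)) {
      Q <- q_absent(cnt)
      for (j in seq_len(P)) {
        others <- Q[-j, , drop = FALSE]
        out[j] <- out[j] +
          sum((1 - Q[j, ]) * apply(others, 2, prod))
      }
    }
  }
  attr(out, "skipped") <- sum(!usable)
  out
}

#' Private-allele rarefaction curve
#'
#' Expected private-allele counts per population for every standardised
#' sample size g from 2 up to `G` gene copies (default 100, the
#' conventional standardisation for comparing populations of unequal
#' size).
#'
#' @inheritParams private_allele_count
#' @param g_max maximum standardised sample size in gene copies.
#' @return data frame with columns `g`, `population`, `expected_private`,
#'   `skipped_loci`.
#' @export
rarefaction_curve <- function(G, pops, g_max = 100) {
  stopifnot(g_max >= 2)
  gs <- 2:g_max
  rows <- lapply(gs, function(g) {
    e <- tryCatch(rarefied_private_alleles(G, pops, g),
                  error = function(cond) NULL)
    if (is.null(e)) return(NULL)
    data.frame(g = g, population = names(e),
               expected_private = as.numeric(e),
               skipped_loci = attr(e, "skipped"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no population has ", 2, " gene copies; cannot rarefy")
  out
}
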