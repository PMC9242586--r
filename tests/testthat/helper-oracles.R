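# Independent oracles used to check the package's own implementations.
# Each deliberately takes the slow, direct route: exhaustive enumeration,
# factorial-formula probabilities, or Monte-Carlo resampling.

# Minimal number of per-haplotype ancestry changes over all phasings
# consistent with an unphased diploid state sequence (0 = coyote hom,
# 1 = het, 2 = red wolf hom). Hets can be phased either way; exhaustive
# over all 2^n_het assignments.
oracle_min_hap_switches <- function(states) {
  states <- states[!is.na(states)]
  if (length(states) < 2) return(0L)
  het <- which(states == 1L)
  base_h1 <- ifelse(states == 2L, 1L, 0L)
  base_h2 <- ifelse(states == 0L, 0L, 1L)
  best <- Inf
  n_h <- length(het)
  for (mask in seq_len(max(1L, 2^n_h)) - 1L) {
    h1 <- base_h1
    h2 <- base_h2
    if (n_h) {
      flip <- as.logical(bitwAnd(mask, 2^(seq_len(n_h) - 1L)))
      h1[het[flip]] <- 1L
      h2[het[flip]] <- 0L
    }
    sw <- sum(h1[-1] != h1[-length(h1)]) + sum(h2[-1] != h2[-length(h2)])
    best <- min(best, sw)
    if (n_h == 0L) break
  }
  as.integer(best)
}

# Exact HWE p-value by full enumeration with factorial-product
# probabilities (conditioning on allele counts): P(h) =
# n! / (nAA! h! naa!) * 2^h / [ (2n)! / (nA! na! ) ].
oracle_hwe_enum <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1)
  hs <- seq.int(nA %% 2, min(nA, na), by = 2)
  prob <- vapply(hs, function(h) {
    aa <- (nA - h) / 2
    bb <- (na - h) / 2
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
          h * log(2) + lfactorial(nA) + lfactorial(na) -
          lfactorial(2 * n))
  }, numeric(1))
  p_obs <- prob[hs == nAa]
  sum(prob[prob <= p_obs * (1 + 1e-9)])
}

# Brute-force private-allele counter: explicit loops over loci, alleles
# and populations.
oracle_private_count <- function(G, pops) {
  upops <- unique(pops)
  out <- stats::setNames(integer(length(upops)), upops)
  for (j in seq_len(ncol(G))) {
    for (allele in c("ref", "alt")) {
      present <- vapply(upops, function(p) {
        g <- G[pops == p, j]
        g <- g[!is.na(g)]
        if (!length(g)) return(FALSE)
        if (allele == "alt") any(g > 0) else any(g < 2)
      }, logical(1))
      if (sum(present) == 1)
        out[which(present)] <- out[which(present)] + 1L
    }
  }
  out
}

# Monte-Carlo subsampling oracle for rarefied private-allele richness:
# per resample, draw g gene copies per population per locus without
# replacement (hypergeometric) and count realised private alleles.
# Returns mean and standard error per population.
oracle_rarefied_mc <- function(G, pops, g, nrep = 1e4, seed = 1) {
  set.seed(seed)
  upops <- unique(pops)
  P <- length(upops)
  tot_priv <- matrix(0, nrep, P, dimnames = list(NULL, upops))
  for (j in seq_len(ncol(G))) {
    alt <- vapply(upops, function(p) {
      gg <- G[pops == p, j]
      sum(gg, na.rm = TRUE)
    }, numeric(1))
    copies <- vapply(upops, function(p) {
      2 * sum(!is.na(G[pops == p, j]))
    }, numeric(1))
    if (any(copies < g)) next
    alt_draw <- vapply(seq_len(P), function(k) {
      stats::rhyper(nrep, alt[k], copies[k] - alt[k], g)
    }, numeric(nrep))
    alt_pres <- alt_draw > 0
    ref_pres <- alt_draw < g
    tot_priv <- tot_priv +
      (alt_pres & rowSums(alt_pres) == 1) +
      (ref_pres & rowSums(ref_pres) == 1)
  }
  list(mean = colMeans(tot_priv),
       se = apply(tot_priv, 2, stats::sd) / sqrt(nrep))
}

# Independent greedy LD pruner at step-1 granularity: recomputes the
# mean-imputed correlation from scratch at every comparison.
oracle_ld_greedy <- function(G, window, r2_thresh) {
  imp <- apply(G, 2, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    col
  })
  maf <- apply(G, 2, function(col) {
    col <- col[!is.na(col)]
    f <- sum(col) / (2 * length(col))
    min(f, 1 - f)
  })
  L <- ncol(G)
  keep <- rep(TRUE, L)
  for (s in seq_len(max(1, L - 1))) {
    e <- min(L, s + window - 1)
    repeat {
      idx <- which(keep[s:e]) + s - 1
      found <- FALSE
      if (length(idx) >= 2) {
        for (a in seq_len(length(idx) - 1)) {
          for (b in (a + 1):length(idx)) {
            i <- idx[a]; j <- idx[b]
            if (stats::sd(imp[, i]) == 0 || stats::sd(imp[, j]) == 0) next
            if (stats::cor(imp[, i], imp[, j])^2 > r2_thresh) {
              drop <- if (maf[i] < maf[j]) i
                      else if (maf[j] < maf[i]) j else j
              keep[drop] <- FALSE
              found <- TRUE
              break
            }
          }
          if (found) break
        }
      }
      if (!found) break
    }
  }
  which(keep)
}
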