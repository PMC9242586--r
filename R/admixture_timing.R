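#' Genetic map lengths used for admixture dating
#'
#' Sex-averaged canid map lengths: 2085 cM for the 38 autosomes and 111 cM
#' for the X chromosome.
#'
#' @param autosomal,x map lengths in centimorgans.
#' @return named list with `autosomal` and `x` (cM).
#' @export
genome_lengths <- function(autosomal = 2085, x = 111) {
  stopifnot(autosomal > 0, x > 0)
  list(autosomal = autosomal, x = x)
}

#' Expected diploid ancestry-switch count under a pulse of admixture
#'
#' Under a single admixture pulse T generations ago with founding
#' proportion z and random mating, the expected number of diploid
#' ancestry-state switches along a genome of genetic length L cM is
#' B = 0.04 T L z (1 - z): each haplotype accumulates junctions at T per
#' Morgan, a junction is an observable ancestry switch with probability
#' 2 z (1 - z), and a diploid carries two haplotypes.
#'
#' @param T generations since the pulse (>= 0).
#' @param L genetic length in centimorgans.
#' @param z founding admixture proportion in \[0, 1\].
#' @return expected switch count.
#' @export
#' @examples
#' expected_switches(10, 2085, 0.5)  # 208.5
expected_switches <- function(T, L, z) {
  stopifnot(all(T >= 0), all(L > 0), all(z >= 0), all(z <= 1))
  0.04 * T * L * z * (1 - z)
}

#' Generations since admixture from a switch count
#'
#' Inverts the pulse-model switch-count equation:
#' T = B / (0.04 L z (1 - z)). Undefined for z of exactly 0 or 1 (an
#' unadmixed genome carries no dating information).
#'
#' @param B observed diploid ancestry-switch count (>= 0).
#' @param L genetic length in centimorgans.
#' @param z ancestry proportion, strictly inside (0, 1).
#' @return estimated generations since admixture.
#' @export
estimate_generations <- function(B, L, z) {
  stopifnot(all(B >= 0), all(L > 0))
  if (any(z <= 0 | z >= 1))
    stop("timing undefined for z = 0 or z = 1 (unadmixed genome)")
  B / (0.04 * L * z * (1 - z))
}

#' Convert generations to calendar years
#'
#' Averages over two canid generation times -- 4 years (the common
#' estimate) and 2 years (allowing first-year breeding) -- giving
#' years = 3 T.
#'
#' @param T generations (>= 0).
#' @return calendar years.
#' @export
generations_to_years <- function(T) {
  stopifnot(all(T >= 0))
  (4 * T + 2 * T) / 2
}

#' Per-sample admixture-timing report
#'
#' Applies the pulse-model dating equation to each sample's autosomal and
#' X-linked switch counts and ancestry proportions. Samples with z
#' outside (0, 1) in a compartment are flagged (`defined = FALSE`) rather
#' than dropped; their generations/years are `NA`, with a
#' fixture-compatibility option to render undefined timing as 0.0, the
#' convention some published tables use.
#'
#' @param summary data frame with columns `sample`, `z_auto`, `B_auto`
#'   and optionally `z_x`, `B_x` (as built by [ancestry_profile()]).
#' @param lengths map lengths from [genome_lengths()].
#' @param undefined_as_zero render undefined timing as 0 instead of `NA`.
#' @return data frame: `sample`, `compartment` (`"autosomal"`/`"x"`),
#'   `B`, `z`, `L`, `generations`, `years`, `defined`.
#' @export
timing_report <- function(summary, lengths = genome_lengths(),
                          undefined_as_zero = FALSE) {
  one <- function(compartment, B, z, L) {
    defined <- !is.na(z) & z > 0 & z < 1 & !is.na(B)
    gen <- rep(NA_real_, length(B))
    gen[defined] <- estimate_generations(B[defined], L, z[defined])
    yrs <- ifelse(defined, generations_to_years(ifelse(defined, gen, 0)), NA)
    if (undefined_as_zero) {
      gen[!defined] <- 0
      yrs[!defined] <- 0
    }
    data.frame(sample = summary$sample, compartment = compartment,
               B = B, z = z, L = L, generations = gen, years = yrs,
               defined = defined, stringsAsFactors = FALSE)
  }
  out <- one("autosomal", summary$B_auto, summary$z_auto,
             lengths$autosomal)
  if (!is.null(summary$z_x))
    out <- rbind(out, one("x", summary$B_x, summary$z_x, lengths$x))
  out
}
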