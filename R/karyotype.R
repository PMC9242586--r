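#' Canid karyotype with genetic and physical chromosome lengths
#'
#' Returns the default karyotype used throughout the package: the 38 canid
#' autosomes plus the X chromosome. Physical lengths approximate the dog
#' reference assembly (CanFam3.1-scale chromosome sizes); genetic lengths
#' are assigned proportionally to physical length and rescaled so that the
#' autosomes total 2085 cM and the X 111 cM, the canid sex-averaged map
#' lengths used for admixture dating. Recombination is therefore uniform
#' per chromosome (a linear cM-bp map), which is the assumption behind the
#' diploid switch-count dating equation.
#'
#' @param autosomal_cM total autosomal genetic length in centimorgans.
#' @param x_cM genetic length of the X chromosome in centimorgans.
#' @return A data frame of class `karyotype` with columns `chrom`
#'   (character), `length_bp` (integer-valued numeric) and `length_cM`
#'   (numeric). The X chromosome is the row named `"X"`.
#' @export
#' @examples
#' k <- canid_karyotype()
#' sum(k$length_cM[k$chrom != "X"])  # 2085
canid_karyotype <- function(autosomal_cM = 2085, x_cM = 111) {
  stopifnot(autosomal_cM > 0, x_cM > 0)
  # approximate CanFam3.1 chromosome sizes, Mb
  auto_mb <- c(122.7, 85.4, 91.9, 88.3, 88.9, 77.6, 80.9, 74.3, 61.1,
               69.3, 74.4, 72.5, 63.4, 60.9, 64.2, 59.6, 64.3, 55.9,
               53.5, 58.2, 50.8, 61.4, 52.3, 47.7, 51.6, 38.9, 45.9,
               41.2, 41.6, 40.2, 39.2, 38.8, 31.4, 42.1, 26.5, 30.8,
               30.9, 23.9)
  x_mb <- 123.9
  cM <- autosomal_cM * auto_mb / sum(auto_mb)
  k <- data.frame(
    chrom = c(as.character(seq_along(auto_mb)), "X"),
    length_bp = round(c(auto_mb, x_mb) * 1e6),
    length_cM = c(cM, x_cM),
    stringsAsFactors = FALSE
  )
  class(k) <- c("karyotype", "data.frame")
  k
}

#' Autosome identifiers of a karyotype
#'
#' @param karyotype a `karyotype` data frame.
#' @param x_chrom chromosome id treated as the X.
#' @return character vector of autosome ids.
#' @export
autosomes <- function(karyotype, x_chrom = "X") {
  setdiff(karyotype$chrom, x_chrom)
}

#' Construct and validate a SNP map
#'
#' A SNP map orders the loci of a dosage or genotype matrix along
#' chromosomes. Positions are 1-based base pairs and must be strictly
#' increasing within each chromosome; an optional centimorgan column gives
#' genetic positions. Chromosome ids must be drawn from the declared
#' karyotype.
#'
#' @param chrom character vector of chromosome ids, one per SNP.
#' @param pos integer-valued vector of 1-based physical positions.
#' @param cM optional numeric genetic positions (centimorgans).
#' @param karyotype karyotype the chromosome ids must belong to; defaults
#'   to [canid_karyotype()].
#' @return data frame of class `snp_map` with columns `chrom`, `pos` and,
#'   when supplied, `cM`; the karyotype is attached as an attribute.
#' @export
#' @examples
#' snp_map(c("1", "1", "2"), c(100L, 200L, 50L))
snp_map <- function(chrom, pos, cM = NULL, karyotype = canid_karyotype()) {
  chrom <- as.character(chrom)
  if (length(chrom) != length(pos))
    stop("chrom and pos must have the same length")
  bad <- setdiff(unique(chrom), karyotype$chrom)
  if (length(bad))
    stop("chromosome ids not in the declared karyotype: ",
         paste(bad, collapse = ", "))
  if (any(pos < 1) || any(pos != floor(pos)))
    stop("positions must be positive 1-based integers")
  m <- data.frame(chrom = chrom, pos = as.numeric(pos),
                  stringsAsFactors = FALSE)
  if (!is.null(cM)) {
    if (length(cM) != length(pos)) stop("cM must match pos in length")
    m$cM <- as.numeric(cM)
  }
  for (cc in unique(chrom)) {
    p <- m$pos[m$chrom == cc]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", cc)
  }
  attr(m, "karyotype") <- karyotype
  class(m) <- c("snp_map", "data.frame")
  m
}

#' Evenly spaced SNP map over a karyotype
#'
#' Lays out SNPs at a fixed density along every chromosome of a karyotype,
#' with a `cM` column from the karyotype's linear cM-bp map. Used to place
#' markers on simulated tract genomes.
#'
#' @param karyotype a `karyotype` data frame.
#' @param per_mb SNP density per megabase.
#' @return a `snp_map` with a `cM` column.
#' @export
even_snp_map <- function(karyotype = canid_karyotype(), per_mb = 25) {
  stopifnot(per_mb > 0)
  pieces <- lapply(seq_len(nrow(karyotype)), function(i) {
    L <- karyotype$length_bp[i]
    n <- max(1L, floor(L / 1e6 * per_mb))
    pos <- round(seq(1, L, length.out = n))
    pos <- unique(pos)
    data.frame(chrom = karyotype$chrom[i], pos = pos,
               cM = pos / L * karyotype$length_cM[i],
               stringsAsFactors = FALSE)
  })
  m <- do.call(rbind, pieces)
  snp_map(m$chrom, m$pos, m$cM, karyotype = karyotype)
}
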