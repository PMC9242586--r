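#' @importFrom utils read.table write.table read.csv
NULL

stop_io <- function(path, ...) {
  stop(sprintf("%s: %s", path, paste0(...)), call. = FALSE)
}

# internal: validate a dosage matrix against its map; values in [0,2]
# within tol, anything further out is rejected with its location.
check_dosage <- function(x, map, path = "<matrix>", tol = 1e-6) {
  if (ncol(x) != nrow(map))
    stop_io(path, sprintf("dosage matrix has %d SNP columns but map has %d",
                          ncol(x), nrow(map)))
  bad <- which(!is.na(x) & (x < -tol | x > 2 + tol), arr.ind = TRUE)
  if (nrow(bad))
    stop_io(path, sprintf(
      "dosage %.6g outside [0,2] at sample row %d, SNP column %d",
      x[bad[1, , drop = FALSE]], bad[1, 1], bad[1, 2]))
  # values within tolerance of the bounds are snapped to the bounds
  x[!is.na(x) & x < 0] <- 0
  x[!is.na(x) & x > 2] <- 2
  x
}

#' Read a per-SNP ancestry dosage matrix
#'
#' Reads a whitespace/tab-delimited dosage matrix as emitted by local
#' ancestry inference software: one value per sample per SNP, each the
#' expected number of haplotypes (0-2) derived from the focal source
#' population. In this package the dosage is polarised to count copies of
#' red wolf ancestry: 0 = homozygous coyote, 2 = homozygous red wolf.
#'
#' With `samples_in = "rows"` (the default layout written by
#' [write_dosage()]) each line is one sample: an id followed by one dosage
#' per SNP. With `samples_in = "cols"` the file is transposed: a header
#' line of sample ids followed by one line per SNP.
#'
#' Values outside \[0, 2\] beyond a 1e-6 tolerance are rejected with their
#' location, never clamped. `NA` marks missing dosages.
#'
#' @param path file to read.
#' @param map `snp_map` whose length must match the SNP dimension.
#' @param samples_in `"rows"` or `"cols"`; declared file orientation.
#' @return numeric matrix, samples in rows (named), SNPs in columns.
#' @export
read_dosage <- function(path, map, samples_in = c("rows", "cols")) {
  samples_in <- match.arg(samples_in)
  if (!file.exists(path)) stop_io(path, "file not found")
  if (samples_in == "rows") {
    tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                      colClasses = c("character", rep(NA, nrow(map))))
    if (!nrow(tab)) stop_io(path, "empty dosage file")
    ids <- tab[[1]]
    x <- as.matrix(tab[, -1, drop = FALSE])
  } else {
    tab <- read.table(path, header = TRUE, check.names = FALSE)
    if (!nrow(tab)) stop_io(path, "empty dosage file")
    ids <- colnames(tab)
    x <- t(as.matrix(tab))
  }
  storage.mode(x) <- "double"
  dimnames(x) <- list(ids, NULL)
  check_dosage(x, map, path)
}

#' Write a dosage matrix
#'
#' Inverse of [read_dosage()] in its `samples_in = "rows"` orientation.
#'
#' @param x dosage matrix, samples in rows.
#' @param path output file.
#' @export
write_dosage <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Average replicate dosage runs
#'
#' Local-ancestry dosages are typically averaged over independent runs of
#' the inference program (e.g. several EM replicates at several assumed
#' admixture times). This takes the elementwise arithmetic mean. A cell
#' missing in any run is missing in the average (missingness propagates;
#' no imputation).
#'
#' @param runs either a list of dosage matrices with identical sample ids
#'   and dimensions, or a character vector of file paths read via
#'   [read_dosage()].
#' @param map `snp_map`, required when `runs` are paths.
#' @param samples_in file orientation, passed to [read_dosage()].
#' @return the mean dosage matrix.
#' @export
average_dosage_runs <- function(runs, map = NULL,
                                samples_in = c("rows", "cols")) {
  if (is.character(runs)) {
    samples_in <- match.arg(samples_in)
    if (is.null(map)) stop("map is required when averaging files")
    runs <- lapply(runs, read_dosage, map = map, samples_in = samples_in)
  }
  if (!length(runs)) stop("no runs to average")
  ref <- runs[[1]]
  for (i in seq_along(runs)) {
    r <- runs[[i]]
    if (!identical(dim(r), dim(ref)) ||
        !identical(rownames(r), rownames(ref)))
      stop("run ", i, " differs in dimensions or sample order")
  }
  acc <- Reduce(`+`, runs)
  acc / length(runs)
}

#' Read a biallelic genotype matrix
#'
#' Reads genotypes as alternate-allele counts in \{0, 1, 2\} with missing
#' cells preserved as `NA`. Two formats are supported: VCF (via
#' \pkg{vcfR}; strictly biallelic, multi-allelic records are rejected) and
#' PLINK-style additive text (`.raw` layout: header
#' `FID IID PAT MAT SEX PHENOTYPE` followed by one column per SNP).
#'
#' @param path file to read.
#' @param format `"vcf"` or `"plink_text"`.
#' @return integer matrix, samples in rows (named), loci in columns
#'   (named).
#' @export
read_genotypes <- function(path, format = c("vcf", "plink_text")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_io(path, "file not found")
  if (file.size(path) == 0) stop_io(path, "empty genotype file")
  if (format == "vcf") {
    v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
    if (!nrow(v@fix)) stop_io(path, "VCF contains no variant records")
    alt <- v@fix[, "ALT"]
    multi <- grepl(",", alt)
    if (any(multi))
      stop_io(path, sprintf("multi-allelic site at %s:%s not supported",
                            v@fix[which(multi)[1], "CHROM"],
                            v@fix[which(multi)[1], "POS"]))
    gt <- vcfR::extract.gt(v, element = "GT")
    counts <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_integer_)
      al <- strsplit(g, "[/|]")[[1]]
      if (any(al == ".")) return(NA_integer_)
      sum(al == "1")
    })
    ids <- paste(v@fix[, "CHROM"], v@fix[, "POS"], sep = ":")
    out <- t(counts)
    colnames(out) <- ids
  } else {
    tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE)
    if (!nrow(tab)) stop_io(path, "no samples in PLINK text file")
    fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(fixed %in% colnames(tab)[seq_len(6)]))
      stop_io(path, "not a PLINK additive text file (missing header)")
    out <- as.matrix(tab[, -(1:6), drop = FALSE])
    storage.mode(out) <- "integer"
    rownames(out) <- tab$IID
  }
  bad <- which(!is.na(out) & !(out %in% 0:2), arr.ind = TRUE)
  if (nrow(bad))
    stop_io(path, sprintf("genotype %s at row %d, column %d not in {0,1,2}",
                          out[bad[1, , drop = FALSE]], bad[1, 1], bad[1, 2]))
  storage.mode(out) <- "integer"
  out
}

#' Write ancestry blocks as BED
#'
#' Internal block coordinates are 1-based inclusive (first to last SNP of
#' the run); BED output is 0-based half-open, so a block spanning bp
#' 100..500 becomes `start 99, end 500`. Records are sorted by sample,
#' chromosome, then start; extra columns carry the ancestry state and SNP
#' count. The conversion is bijective with [read_blocks_bed()].
#'
#' @param blocks block table as returned by [segment_blocks()].
#' @param path output file.
#' @export
write_blocks_bed <- function(blocks, path) {
  req <- c("sample", "chrom", "start", "end", "state", "n_snp")
  if (!all(req %in% names(blocks)))
    stop("blocks must have columns ", paste(req, collapse = ", "))
  for (key in split(seq_len(nrow(blocks)),
                    paste(blocks$sample, blocks$chrom))) {
    if (is.unsorted(blocks$start[key]))
      stop("blocks are not sorted by start within sample/chromosome")
  }
  ord <- order(blocks$sample, blocks$chrom, blocks$start)
  b <- blocks[ord, , drop = FALSE]
  out <- data.frame(chrom = b$chrom, start = b$start - 1L, end = b$end,
                    sample = b$sample, state = b$state, n_snp = b$n_snp)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read ancestry blocks from BED
#'
#' @param path BED file written by [write_blocks_bed()].
#' @return block table with 1-based inclusive `start`/`end` and
#'   recomputed `length_mb`.
#' @export
read_blocks_bed <- function(path) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "start", "end", "sample",
                                  "state", "n_snp"))
  data.frame(sample = tab$sample, chrom = as.character(tab$chrom),
             start = tab$start + 1L, end = tab$end,
             state = tab$state, n_snp = as.integer(tab$n_snp),
             length_mb = (tab$end - (tab$start + 1L)) / 1e6,
             stringsAsFactors = FALSE)
}

#' Read a SNP map file
#'
#' Tab-delimited with header columns `chrom`, `pos` and optionally `cM`.
#'
#' @param path file to read.
#' @param karyotype karyotype the chromosomes must belong to.
#' @return a `snp_map`.
#' @export
read_snp_map <- function(path, karyotype = canid_karyotype()) {
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
  snp_map(tab$chrom, tab$pos, cM = tab[["cM"]], karyotype = karyotype)
}

#' Write a SNP map file
#' @param map a `snp_map`.
#' @param path output file.
#' @export
write_snp_map <- function(map, path) {
  write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' CSV with columns `id`, `region`, `sex`, `age_class` (pup, juvenile,
#' adult) and optional `weight` (kg, must be positive when present).
#'
#' @param path file to read.
#' @return validated data frame.
#' @export
read_metadata <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("id", "region", "sex", "age_class")
  if (!all(req %in% names(tab)))
    stop_io(path, "metadata needs columns ", paste(req, collapse = ", "))
  ok_age <- tab$age_class %in% c("pup", "juvenile", "adult") |
    is.na(tab$age_class)
  if (!all(ok_age))
    stop_io(path, "invalid age class: ", tab$age_class[!ok_age][1])
  if (!is.null(tab$weight) && any(!is.na(tab$weight) & tab$weight <= 0))
    stop_io(path, "weights must be positive")
  tab
}

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "ghostancestry")
  if (p == "") stop("bundled fixture not found: ", name)
  p
}

#' Published per-sample ancestry and timing table (31 SWLA coyotes)
#'
#' Per-sample autosomal and X-linked red wolf ancestry proportions and
#' admixture timing in years, transcribed from the published study table.
#' One printed value is corrected: sample CL12980's autosomal timing was
#' printed "209." and is stored as 20.9 (the only reading consistent with
#' the column scale and the printed parish mean); the correction note is
#' attached as attribute `"correction"`.
#'
#' @return data frame with columns `sample`, `parish`, `prop_auto`,
#'   `prop_x`, `timing_auto_years`, `timing_x_years`.
#' @export
swla_ancestry_table <- function() {
  tab <- read.csv(fixture_path("table1_ancestry_timing.csv"),
                  comment.char = "#", stringsAsFactors = FALSE)
  attr(tab, "correction") <-
    "CL12980 timing_auto_years printed '209.', stored as 20.9"
  tab
}

#' Published per-sample autosomal block-size table (31 SWLA coyotes)
#'
#' Average autosomal ancestry block sizes (Mb) per coyote for the three
#' ancestry states (coyote, joint = heterozygous, red wolf), with the
#' Cameron parish NW/NE/SW subregion labels.
#'
#' @return data frame with columns `sample`, `parish`, `subregion`,
#'   `coyote_mb`, `joint_mb`, `redwolf_mb`.
#' @export
swla_blocks_table <- function() {
  read.csv(fixture_path("table2_block_sizes.csv"),
           comment.char = "#", stringsAsFactors = FALSE,
           na.strings = c("NA", ""))
}

#' Published 1970s Texas canid table
#'
#' Sample information for the 10 Texas canids from the 1970s red wolf
#' founder capture efforts, with previously published red wolf ancestry
#' proportions.
#'
#' @return data frame with columns `sample`, `county`, `rw_ancestry`,
#'   `collection_date`, `starred`.
#' @export
texas_canids_table <- function() {
  read.csv(fixture_path("table3_texas_canids.csv"),
           comment.char = "#", stringsAsFactors = FALSE)
}

#' Joined cohort table of ancestry, timing, and block sizes
#'
#' Joins the ancestry/timing table with the block-size table by sample id.
#' Subregion labels (NW/NE/SW Cameron) are carried from the block-size
#' table, the only place they are printed, and a `group` column combines
#' parish and subregion (e.g. `"Cameron-NW"`).
#'
#' @return merged data frame, one row per coyote.
#' @export
swla_cohort_table <- function() {
  a <- swla_ancestry_table()
  b <- swla_blocks_table()
  m <- merge(a, b[, c("sample", "subregion", "coyote_mb", "joint_mb",
                      "redwolf_mb")], by = "sample", sort = TRUE)
  m$group <- ifelse(is.na(m$subregion), m$parish,
                    paste(m$parish, m$subregion, sep = "-"))
  m
}
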