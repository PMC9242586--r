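# small builders shared across test files

# snp map with evenly spaced positions on one chromosome
toy_map <- function(n, chrom = "1", spacing = 1e6, start = 1e6) {
  snp_map(rep(chrom, n), seq(start, by = spacing, length.out = n))
}

# blocks from one unphased diploid state sequence (codes 0/1/2, NA ok)
blocks_from_states <- function(states, map = toy_map(length(states))) {
  m <- matrix(as.integer(states), nrow = 1,
              dimnames = list("s1", NULL))
  segment_blocks(m, map)
}

# minimal biallelic VCF writer for reader tests
write_mini_vcf <- function(path, gts, chrom = "1",
                           pos = seq_len(ncol(gts)) * 100,
                           alt = rep("T", ncol(gts))) {
  samples <- rownames(gts)
  lines <- c("##fileformat=VCFv4.2",
             paste0("##contig=<ID=", chrom, ">"),
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", samples),
                   collapse = "\t"))
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(ncol(gts))) {
    g <- ifelse(is.na(gts[, j]), "./.", code[as.character(gts[, j])])
    lines <- c(lines, paste(c(chrom, pos[j], paste0("snp", j), "A",
                              alt[j], ".", "PASS", ".", "GT", g),
                            collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

# matching PLINK additive text (.raw layout) for the same genotypes
write_mini_raw <- function(path, gts) {
  header <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
              paste0("snp", seq_len(ncol(gts)), "_T"))
  rows <- vapply(seq_len(nrow(gts)), function(i) {
    paste(c(rownames(gts)[i], rownames(gts)[i], 0, 0, 0, -9,
            ifelse(is.na(gts[i, ]), "NA", gts[i, ])), collapse = " ")
  }, character(1))
  writeLines(c(paste(header, collapse = " "), rows), path)
  path
}
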