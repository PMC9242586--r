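test_that("dosage files round-trip in both orientations", {
  map <- toy_map(3)
  D <- matrix(c(0, 1, 2, 2, 1, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  f <- withr::local_tempfile()
  write_dosage(D, f)
  expect_equal(read_dosage(f, map), D)

  f2 <- withr::local_tempfile()
  writeLines(c("a\tb", "0\t2", "1\t1", "2\t0"), f2)
  expect_equal(read_dosage(f2, map, samples_in = "cols"), D)
})

test_that("out-of-range dosages are rejected with their location", {
  map <- toy_map(2)
  f <- withr::local_tempfile()
  writeLines("a\t0.5\t2.5", f)
  expect_error(read_dosage(f, map), "2\\.5.*row 1.*column 2")
  writeLines("a\t0.5\t1.5\t1.0", f)
  expect_error(read_dosage(f, map), "columns")  # dimension mismatch
})

test_that("replicate-run averaging is an elementwise mean", {
  map <- toy_map(4)
  set.seed(11)
  runs <- replicate(3, matrix(runif(12, 0, 2), nrow = 3,
                              dimnames = list(c("a", "b", "c"), NULL)),
                    simplify = FALSE)
  avg <- average_dosage_runs(runs)
  # independent summation oracle
  want <- (runs[[1]] + runs[[2]] + runs[[3]]) / 3
  manual <- matrix(0, 3, 4)
  for (r in runs) manual <- manual + r / length(runs)
  expect_equal(avg, want, tolerance = 1e-12)
  expect_equal(unname(avg), manual, tolerance = 1e-12, ignore_attr = TRUE)

  # idempotence over identical runs
  expect_equal(average_dosage_runs(rep(runs[1], 12)), runs[[1]])

  # midpoint of 0 and 2 is 1; missing in any run propagates
  a <- matrix(c(0, NA), 1, dimnames = list("s", NULL))
  b <- matrix(c(2, 1), 1, dimnames = list("s", NULL))
  expect_equal(unname(average_dosage_runs(list(a, b))),
               matrix(c(1, NA), 1))

  bad <- runs[[1]][c(2, 1, 3), ]
  expect_error(average_dosage_runs(list(runs[[1]], bad)), "sample order")
})

test_that("VCF genotypes decode to alternate-allele counts", {
  gts <- matrix(c(0L, 1L, 2L, NA), nrow = 4,
                dimnames = list(c("s1", "s2", "s3", "s4"), NULL))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf(f, gts)
  G <- read_genotypes(f, "vcf")
  expect_identical(unname(G[, 1]), c(0L, 1L, 2L, NA))
  expect_identical(rownames(G), rownames(gts))
})

test_that("PLINK text and VCF paths agree; degenerate files error", {
  set.seed(21)
  gts <- matrix(sample(c(0:2, NA), 24, replace = TRUE), nrow = 4,
                dimnames = list(paste0("s", 1:4), NULL))
  fv <- withr::local_tempfile(fileext = ".vcf")
  fr <- withr::local_tempfile(fileext = ".raw")
  write_mini_vcf(fv, gts)
  write_mini_raw(fr, gts)
  expect_equal(unname(read_genotypes(fv, "vcf")),
               unname(read_genotypes(fr, "plink_text")))

  fe <- withr::local_tempfile()
  file.create(fe)
  expect_error(read_genotypes(fe, "vcf"), "empty")

  fm <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf(fm, gts[, 1, drop = FALSE], alt = "T,C")
  expect_error(read_genotypes(fm, "vcf"), "multi-allelic")
})

test_that("BED export is 0-based half-open, sorted, and bijective", {
  blocks <- blocks_from_states(c(2, 2, 2),
                               toy_map(3, spacing = 200, start = 100))
  f <- withr::local_tempfile(fileext = ".bed")
  write_blocks_bed(blocks, f)
  bed <- read.table(f)
  expect_equal(bed$V2, 99)   # 1-based 100 -> 0-based 99
  expect_equal(bed$V3, 500)  # half-open end = last bp

  back <- read_blocks_bed(f)
  expect_equal(back$start, blocks$start)
  expect_equal(back$end, blocks$end)
  expect_equal(back$state, blocks$state)

  # interleaved chromosomes come out sorted
  m2 <- snp_map(c("2", "1"), c(1000, 500))
  two <- segment_blocks(matrix(c(0L, 2L), 1,
                               dimnames = list("s1", NULL)), m2)
  write_blocks_bed(two, f)
  out <- read.table(f)
  expect_equal(as.character(out$V1), c("1", "2"))

  unsorted <- blocks[c(1, 1), ]
  unsorted$start <- c(500, 100)
  unsorted$end <- c(600, 200)
  expect_error(write_blocks_bed(unsorted, f), "sorted")
})

test_that("bundled tables match the printed values and pinned checksums", {
  sums <- tools::md5sum(vapply(
    c("table1_ancestry_timing.csv", "table2_block_sizes.csv",
      "table3_texas_canids.csv"),
    function(f) system.file("extdata", f, package = "ghostancestry"),
    character(1)))
  expect_equal(unname(sums),
               c("0fcdeecf49f3ac429c7e720c3d53a48f",
                 "e0b70cac16b18c0fc2f54da2f2db4366",
                 "41251d87b7cccdf19604b4e32594dcbc"))

  t1 <- swla_ancestry_table()
  expect_equal(nrow(t1), 31)
  expect_equal(t1$prop_auto[t1$sample == "CL12923"], 0.629)
  expect_equal(t1$prop_x[t1$sample == "CL12927"], 1.000)
  expect_equal(t1$timing_auto_years[t1$sample == "CL12980"], 20.9)
  expect_match(attr(t1, "correction"), "CL12980")

  t2 <- swla_blocks_table()
  expect_equal(nrow(t2), 31)
  expect_equal(t2$redwolf_mb[t2$sample == "CL12923"], 122.6)
  expect_equal(sum(t2$subregion == "NW", na.rm = TRUE), 8)

  t3 <- texas_canids_table()
  expect_equal(nrow(t3), 10)
  expect_equal(t3$rw_ancestry[t3$sample == "70-TX-04"], 0.52)

  cohort <- swla_cohort_table()
  expect_equal(nrow(cohort), 31)
  expect_equal(cohort$group[cohort$sample == "CL12923"], "Cameron-NW")
  expect_equal(cohort$group[cohort$sample == "CL12935"],
               "Jefferson Davis")
})

test_that("snp maps validate ordering and karyotype membership", {
  expect_error(snp_map(c("1", "1"), c(200, 100)), "increasing")
  expect_error(snp_map("chr99", 100), "karyotype")
  m <- read_snp_map(withr::local_tempfile(lines = c(
    "chrom\tpos\tcM", "1\t100\t0.01", "1\t200\t0.02")))
  expect_s3_class(m, "snp_map")
  expect_equal(m$cM, c(0.01, 0.02))
})
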