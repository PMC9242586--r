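#' Run the ghost-ancestry pipeline
#'
#' Orchestrates the analysis stages over a single declarative
#' configuration: optional tract-genome simulation, dosage-based ancestry
#' profiling with timing, genotype QC, private-allele diversity, the
#' bundled-table regional summary, and the morphology model ranking.
#' Stages run only when their inputs are configured; any stage failure
#' aborts with a stage-named error. All outputs are plain TSV/BED files
#' under `output_dir`, plus a YAML manifest recording the package
#' version, seed, a hash of the configuration, and a checksum per output
#' file -- rerunning the same configuration reproduces identical outputs
#' and manifest hash.
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Recognised components:
#'   \describe{
#'     \item{output_dir}{required output directory.}
#'     \item{seed}{integer seed used by any stochastic stage.}
#'     \item{simulate}{list of [sim_config()] arguments (minus seed):
#'       simulate a cohort, write its dosage matrix and SNP map, and feed
#'       them to the ancestry stage.}
#'     \item{dosage}{list with `path`, `map` (SNP map file) and optional
#'       `samples_in`: analyse an existing dosage matrix.}
#'     \item{classify}{optional list with `het_low`, `het_high`.}
#'     \item{lengths}{optional list with `autosomal`, `x` map lengths
#'       (cM).}
#'     \item{genotypes}{list with `path`, `format`, optional `pops`
#'       (named population label per sample) for the QC and diversity
#'       stages.}
#'     \item{qc}{list of [qc_config()] arguments plus optional
#'       `neutral`.}
#'     \item{diversity}{list with `g` (rarefaction sample size).}
#'     \item{metadata}{metadata CSV path for the morphology stage
#'       (joined to the ancestry stage's per-sample summary by id).}
#'     \item{fixtures}{logical: write the bundled-table regional
#'       summary.}
#'   }
#' @return invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$output_dir)) stop("config needs an output_dir")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out_path <- function(f) file.path(config$output_dir, f)
  results <- list()
  outputs <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(cond) {
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(cond), call. = FALSE)
    })
  }

  D <- NULL
  map <- NULL
  if (!is.null(config$simulate)) {
    stage("simulate", {
      args <- config$simulate
      args$seed <- config$seed %||% stop("simulate stage needs a seed")
      cfg <- do.call(sim_config, args)
      cohort <- simulate_pulse_admixture(cfg)
      map <- even_snp_map(cfg$karyotype, cfg$snp_per_mb)
      D <- tracts_to_dosage(cohort, map)
      write_dosage(D, out_path("dosage.tsv"))
      write_snp_map(map, out_path("snp_map.tsv"))
      outputs <- c(outputs, "dosage.tsv", "snp_map.tsv")
      results$simulate <- list(cfg = cfg,
                                true_z = tract_ancestry_fraction(cohort))
    })
  } else if (!is.null(config$dosage)) {
    stage("read_dosage", {
      if (!file.exists(config$dosage$path))
        stop("dosage file not found: ", config$dosage$path)
      map <- read_snp_map(config$dosage$map)
      D <- read_dosage(config$dosage$path, map,
                        samples_in = config$dosage$samples_in %||% "rows")
    })
  }

  if (!is.null(D)) {
    stage("ancestry", {
      cl <- config$classify %||% list()
      len <- config$lengths %||% list()
      prof <- ancestry_profile(
        D, map, het_low = cl$het_low %||% 0.8,
        het_high = cl$het_high %||% 1.8,
        lengths = genome_lengths(len$autosomal %||% 2085,
                                 len$x %||% 111))
      write.table(summary(prof), out_path("ancestry_summary.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(prof$timing, out_path("timing.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write_blocks_bed(prof$blocks, out_path("blocks.bed"))
      outputs <- c(outputs, "ancestry_summary.tsv", "timing.tsv",
                    "blocks.bed")
      results$ancestry <- prof
    })
  }

  G <- NULL
  if (!is.null(config$genotypes)) {
    stage("qc", {
      if (!file.exists(config$genotypes$path))
        stop("genotype file not found: ", config$genotypes$path)
      G0 <- read_genotypes(config$genotypes$path,
                           format = config$genotypes$format %||% "vcf")
      qc_args <- config$qc %||% list()
      neutral <- isTRUE(qc_args$neutral)
      qc_args$neutral <- NULL
      cfg <- do.call(qc_config, qc_args)
      G <- run_qc(G0, cfg, neutral = neutral)
      write_qc_report(G, out_path("qc_report.tsv"))
      outputs <- c(outputs, "qc_report.tsv")
      results$qc <- list(n_in = ncol(G0), n_out = ncol(G))
    })
  }

  if (!is.null(G) && !is.null(config$genotypes$pops)) {
    stage("diversity", {
      pops <- unlist(config$genotypes$pops)[rownames(G)]
      counts <- private_allele_count(G, pops)
      g <- config$diversity$g %||% 100
      g <- min(g, 2 * min(table(pops)))
      rare <- rarefied_private_alleles(G, pops, g)
      tab <- data.frame(population = names(counts),
                        private_alleles = as.integer(counts),
                        rarefied_expected = as.numeric(rare),
                        g = g)
      write.table(tab, out_path("diversity.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, "diversity.tsv")
      results$diversity <- tab
    })
  }

  if (isTRUE(config$fixtures)) {
    stage("summarize", {
      s <- swla_regional_summary()
      flat <- data.frame(
        quantity = c("prop_auto_mean", "prop_x_mean",
                     "noncameron_prop_auto_mean",
                     "noncameron_prop_x_mean",
                     "cameron_timing_auto_mean",
                     "nw_prop_auto_mean", "nw_timing_auto_mean",
                     "nw_redwolf_block_mean", "nw_redwolf_block_sd",
                     "nw_block_ratio", "ne_block_ratio",
                     "jd_redwolf_block_mean"),
        value = c(s$overall$prop_auto_mean, s$overall$prop_x_mean,
                  s$noncameron$prop_auto_mean, s$noncameron$prop_x_mean,
                  s$cameron$timing_auto_mean,
                  s$ancestry_by_group$mean[
                    s$ancestry_by_group$group == "Cameron-NW"],
                  s$timing_by_group$mean[
                    s$timing_by_group$group == "Cameron-NW"],
                  s$redwolf_blocks_by_group$mean[
                    s$redwolf_blocks_by_group$group == "Cameron-NW"],
                  s$redwolf_blocks_by_group$sd[
                    s$redwolf_blocks_by_group$group == "Cameron-NW"],
                  s$block_ratio_nw, s$block_ratio_ne,
                  s$redwolf_blocks_by_group$mean[
                    s$redwolf_blocks_by_group$group == "Jefferson Davis"]))
      write.table(flat, out_path("regional_summary.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, "regional_summary.tsv")
      results$summarize <- s
    })
  }

  if (!is.null(config$metadata) && !is.null(results$ancestry)) {
    stage("morphology", {
      if (!file.exists(config$metadata))
        stop("metadata file not found: ", config$metadata)
      meta <- read_metadata(config$metadata)
      summ <- results$ancestry$summary
      dat <- merge(meta, summ, by.x = "id", by.y = "sample")
      fit <- fit_morphology_models(dat)
      write.table(fit$table, out_path("morphology_models.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, "morphology_models.tsv")
      results$morphology <- fit
    })
  }

  # the hash covers the analytical configuration, not where results land,
  # so reruns into different directories compare equal
  cfg_for_hash <- config[setdiff(names(config), "output_dir")]
  manifest <- list(
    package = "ghostancestry",
    version = as.character(utils::packageVersion("ghostancestry")),
    seed = config$seed %||% NA,
    config_hash = hash_object(cfg_for_hash),
    outputs = as.list(stats::setNames(
      tools::md5sum(file.path(config$output_dir, outputs)), outputs)))
  manifest$manifest_hash <- hash_object(manifest)
  yaml::write_yaml(manifest, out_path("manifest.yaml"))
  results$manifest <- manifest
  invisible(results)
}

# deterministic md5 of an R object via its canonical YAML rendering
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  yaml::write_yaml(x, f)
  unname(tools::md5sum(f))
}
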