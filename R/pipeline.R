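#' Pipeline configuration
#'
#' One declarative object driving the whole chain: simulate -> qc -> scan
#' -> project -> validate -> enrich -> deltaaf. The master seed propagates
#' to every stochastic stage, so a rerun with the same configuration
#' reproduces byte-identical outputs.
#'
#' @param sim A [sim_config()]; its seed is overridden by `seed`.
#' @param qc A [qc_params()].
#' @param bin_width,step,min_snp,alpha,merge_gap Scan parameters (see
#'   [window_stats()], [call_outliers()], [merge_regions()]).
#' @param min_match,min_back_overlap Projection parameters (see
#'   [project_intervals()], [reciprocal_filter()]).
#' @param n_shuffles Randomizations for the empirical overlap p-values.
#' @param promoter_recovery,enhancer_recovery Peak-simulation recovery
#'   fractions for the promoter-mark and enhancer-mark peak sets.
#' @param n_noise_peaks Decoy peaks per simulated peak set.
#' @param daf_bin_width,daf_threshold Delta-AF binning and the
#'   high-divergence consequence-scan cutoff.
#' @param perturb_delta Shift used by the exonic perturbation control.
#' @param stages Character vector of stages to run, in dependency order.
#' @param seed Master integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            qc = qc_params(),
                            bin_width = 20000L, step = 10000L,
                            min_snp = 20L, alpha = 0.001,
                            merge_gap = 50000L,
                            min_match = 0.1, min_back_overlap = 0.5,
                            n_shuffles = 200L,
                            promoter_recovery = 0.85,
                            enhancer_recovery = 0.71,
                            n_noise_peaks = 500L,
                            daf_bin_width = 0.1, daf_threshold = 0.8,
                            perturb_delta = 0.5,
                            stages = c("simulate", "qc", "scan",
                                       "project", "validate", "enrich",
                                       "deltaaf"),
                            seed = 1L) {
  structure(list(sim = sim, qc = qc, bin_width = bin_width, step = step,
                 min_snp = min_snp, alpha = alpha, merge_gap = merge_gap,
                 min_match = min_match,
                 min_back_overlap = min_back_overlap,
                 n_shuffles = n_shuffles,
                 promoter_recovery = promoter_recovery,
                 enhancer_recovery = enhancer_recovery,
                 n_noise_peaks = n_noise_peaks,
                 daf_bin_width = daf_bin_width,
                 daf_threshold = daf_threshold,
                 perturb_delta = perturb_delta,
                 stages = stages, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of the YAML override the defaults of
#' [pipeline_config()]; `sim:` and `qc:` sub-maps override the respective
#' sub-configurations.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$layout))
    sim_args$layout <- genome_layout(vapply(sim_args$layout, `[[`, "", 1),
                                     vapply(sim_args$layout,
                                            function(x) as.numeric(x[[2]]),
                                            1))
  if (!is.null(sim_args$sweeps))
    sim_args$sweeps <- lapply(sim_args$sweeps, function(s)
      do.call(sweep_spec, s))
  y$sim <- do.call(sim_config, sim_args)
  y$qc <- do.call(qc_params, y$qc %||% list())
  if (!is.null(y$seed)) y$sim$seed <- as.integer(y$seed)
  do.call(pipeline_config, y)
}

## internal: stage logger (structured messages to stderr)
log_stage <- function(...) {
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

## internal: write a TSV deterministically
write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes the configured stages in dependency order, writing every table
#' as TSV and every interval set as BED under `out_dir`, and finishes with
#' a manifest listing each output file with its MD5 checksum and the
#' configuration hash. A rerun with the same configuration and seed
#' reproduces byte-identical outputs. A failing stage aborts with the
#' stage named; outputs of completed stages are retained next to a
#' `FAILED_<stage>` marker file.
#'
#' @param cfg A [pipeline_config()] or path to a YAML file for
#'   [read_pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results of each stage and
#'   `manifest` (data.frame of files and checksums).
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg$sim$seed <- cfg$seed
  cfg_yaml <- yaml::as.yaml(cfg[setdiff(names(cfg), c("sim", "qc"))])
  cfg_hash <- substr(digest_string(cfg_yaml), 1, 12)
  files <- character()
  add <- function(path) files <<- c(files, path)
  res <- list(config = cfg)
  lay <- cfg$sim$layout
  stage <- "none"
  on_fail <- function(e) {
    writeLines(conditionMessage(e),
               file.path(out_dir, paste0("FAILED_", stage)))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    run <- function(s) s %in% cfg$stages
    skip <- function(s) log_stage("stage ", s, ": skipped (toggled off)")

    stage <- "simulate"
    if (run(stage)) {
      log_stage("stage simulate: genotypes, features, peaks, chains")
      res$variants <- simulate_variants(cfg$sim)
      res$features <- simulate_features(cfg$sim)
      res$peaks_promoter <- simulate_peaks(
        res$features$TssA, cfg$promoter_recovery, cfg$n_noise_peaks,
        lay, seed = cfg$seed + 11L, class = "H3K4me3_peak")
      res$peaks_enhancer <- simulate_peaks(
        res$features$Enh, cfg$enhancer_recovery, cfg$n_noise_peaks,
        lay, seed = cfg$seed + 12L, class = "H3K27ac_peak")
      res$chains <- simulate_chain(lay, indel_rate = 1e-5,
                                   seed = cfg$seed + 13L)
      add(write_vcf(res$variants, file.path(out_dir, "variants.vcf"), lay))
      add(write_genome_layout(lay, file.path(out_dir, "genome.tsv")))
      for (nm in names(res$features))
        add(write_bed(res$features[[nm]],
                      file.path(out_dir, paste0("feature_", nm, ".bed"))))
      add(write_bed(res$peaks_promoter,
                    file.path(out_dir, "peaks_promoter.bed")))
      add(write_bed(res$peaks_enhancer,
                    file.path(out_dir, "peaks_enhancer.bed")))
      add(write_chain(res$chains$forward,
                      file.path(out_dir, "chains_forward.chain")))
      add(write_chain(res$chains$backward,
                      file.path(out_dir, "chains_backward.chain")))
    } else skip(stage)

    stage <- "qc"
    if (run(stage)) {
      log_stage("stage qc: filter cascade")
      qc <- apply_qc(res$variants, cfg$qc)
      res$qc_report <- qc$report
      res$variants_qc <- qc$variants
      ## the raw table and the depth matrix are no longer needed in
      ## memory; the VCF on disk retains them
      res$variants <- NULL
      res$variants_qc$depth <- NULL
      rm(qc)
      add(write_qc_report(res$qc_report,
                          file.path(out_dir, "qc_report.tsv")))
    } else {
      skip(stage)
      res$variants_qc <- res$variants
    }

    stage <- "scan"
    if (run(stage)) {
      log_stage("stage scan: FST/diversity windows, outliers, regions")
      w <- window_stats(res$variants_qc, lay, cfg$bin_width, cfg$step,
                        cfg$min_snp)
      w <- call_outliers(w, cfg$alpha)
      res$windows <- w
      res$thresholds <- attr(w, "thresholds")
      res$regions <- assign_genes(
        merge_regions(w, cfg$merge_gap, "domestic"), res$features$gene)
      res$shared <- shared_polymorphism_summary(res$variants_qc)
      res$af_cor <- af_correlation(res$variants_qc)
      add(write_tsv(as.data.frame(w), file.path(out_dir, "windows.tsv")))
      fl <- w[w$outlier & !is.na(w$direction), , drop = FALSE]
      add(write_bed(feature_set(fl$chrom, fl$start, fl$end,
                                name = fl$direction, class = "sweep_bin",
                                source = "sweep_bin"),
                    file.path(out_dir, "outlier_bins.bed")))
      add(write_tsv(res$regions, file.path(out_dir, "sweep_regions.tsv")))
      add(write_tsv(data.frame(
        statistic = c("fst_threshold", "ln_ratio_threshold",
                      "z_cutoff", "shared_pct_of_domestic",
                      "af_correlation_r", "n_outlier_bins",
                      "n_regions"),
        value = c(res$thresholds$fst, res$thresholds$ln_ratio,
                  res$thresholds$z, res$shared$pct_shared_of_domestic,
                  res$af_cor$r, sum(fl$direction == "domestic"),
                  nrow(res$regions))),
        file.path(out_dir, "scan_summary.tsv")))
    } else skip(stage)

    stage <- "project"
    if (run(stage)) {
      log_stage("stage project: reciprocal chain projection")
      prj <- reciprocal_project(res$features$TssA, res$chains$forward,
                                res$chains$backward, cfg$min_match,
                                cfg$min_back_overlap)
      res$projection <- prj
      add(write_tsv(prj$forward, file.path(out_dir,
                                           "projection_status.tsv")))
      add(write_bed(prj$retained, file.path(out_dir,
                                            "projected_TssA.bed")))
    } else skip(stage)

    stage <- "validate"
    if (run(stage)) {
      log_stage("stage validate: recovery rates and shuffle nulls")
      res$recovery_promoter <- recovery_rate(res$features$TssA,
                                             res$peaks_promoter)
      res$recovery_enhancer <- recovery_rate(res$features$Enh,
                                             res$peaks_enhancer)
      res$overlap_p_promoter <- empirical_overlap_p(
        res$features$TssA, res$peaks_promoter, lay, cfg$n_shuffles,
        seed = cfg$seed + 21L)
      res$overlap_p_enhancer <- empirical_overlap_p(
        res$features$Enh, res$peaks_enhancer, lay, cfg$n_shuffles,
        seed = cfg$seed + 22L)
      add(write_tsv(data.frame(
        set = c("promoter", "enhancer"),
        recovery_pct = c(res$recovery_promoter$percent,
                         res$recovery_enhancer$percent),
        n_query = c(res$recovery_promoter$n_query,
                    res$recovery_enhancer$n_query),
        n_hit = c(res$recovery_promoter$n_hit,
                  res$recovery_enhancer$n_hit),
        empirical_p = c(res$overlap_p_promoter$p,
                        res$overlap_p_enhancer$p)),
        file.path(out_dir, "validation.tsv")))
    } else skip(stage)

    stage <- "enrich"
    if (run(stage)) {
      log_stage("stage enrich: locus-overlap Fisher tests")
      w <- res$windows
      unmasked <- !is.na(w$mean_fst)
      universe <- feature_set(w$chrom[unmasked], w$start[unmasked],
                              w$end[unmasked], class = "universe_bin",
                              source = "sweep_bin")
      ref <- w$outlier & !is.na(w$direction) & w$direction == "domestic"
      reference <- feature_set(w$chrom[ref], w$start[ref], w$end[ref],
                               class = "outlier_bin",
                               source = "sweep_bin")
      qsets <- c(res$features[c("TssA", "TxFlnk", "Tx", "EnhG", "Enh",
                                "proximal", "distal", "CDS")],
                 list(H3K4me3_peak = res$peaks_promoter,
                      H3K27ac_peak = res$peaks_enhancer))
      res$enrichment <- locus_overlap_enrichment(qsets, reference,
                                                 universe)
      add(write_tsv(as.data.frame(res$enrichment),
                    file.path(out_dir, "enrichment.tsv")))
    } else skip(stage)

    stage <- "deltaaf"
    if (run(stage)) {
      log_stage("stage deltaaf: divergence bins, M-values, controls")
      daf <- delta_af(res$variants_qc)
      res$daf <- daf
      res$mvalues <- mvalue_table(
        daf, res$features[c("gene", "CDS", "intron", "UTR", "TssA",
                            "Enh")],
        cfg$daf_bin_width, by_consequence = TRUE)
      res$consequences <- consequence_scan(daf, cfg$daf_threshold)
      perturbed <- perturb_exonic_af(daf, res$features$CDS,
                                     cfg$perturb_delta)
      res$mvalues_perturbed <- mvalue_table(
        perturbed, res$features[c("gene", "CDS", "intron", "UTR",
                                  "TssA", "Enh")], cfg$daf_bin_width)
      add(write_tsv(data.frame(bin = colnames(res$mvalues$counts),
                               n_snp = res$mvalues$total),
                    file.path(out_dir, "daf_bins.tsv")))
      add(write_tsv(data.frame(feature = rownames(res$mvalues$M),
                               round(res$mvalues$M, 4),
                               check.names = FALSE),
                    file.path(out_dir, "daf_mvalues.tsv")))
      add(write_tsv(res$mvalues$chisq,
                    file.path(out_dir, "daf_chisq.tsv")))
      add(write_tsv(data.frame(
        consequence = names(res$consequences$counts),
        n = res$consequences$counts),
        file.path(out_dir, "daf_consequences.tsv")))
      add(write_tsv(data.frame(feature = rownames(res$mvalues_perturbed$M),
                               round(res$mvalues_perturbed$M, 4),
                               check.names = FALSE),
                    file.path(out_dir, "daf_mvalues_perturbed.tsv")))
    } else skip(stage)
  }, error = on_fail)

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         config_hash = cfg_hash,
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  log_stage("pipeline complete: ", length(files), " output file(s), ",
            "config hash ", cfg_hash)
  res$manifest <- manifest
  invisible(res)
}

## internal: content hash used to tag manifests with a configuration
## fingerprint (md5 of the serialized text)
digest_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}
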