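# End-to-end orchestration: simulate (or load) -> ICR QC -> baseline
# differential -> DMR discovery -> longitudinal dynamics, with a
# machine-readable run summary. QC-flagged samples are excluded from all
# downstream stages but retained, with reasons, in the QC table.

#' Run the full analysis pipeline
#'
#' @param cohort A `sperm_cohort` from [simulate_cohort()], or a list with
#'   elements `beta`, `manifest`, `annotation`, `regions` assembled from
#'   files.
#' @param config An [analysis_config()].
#' @param out_dir Optional directory; when given, stage outputs (QC table,
#'   per-probe results, top-k list, DMR tables, longitudinal report and a
#'   JSON run summary) are written there with deterministic column order.
#' @return List of class `pipeline_run` with elements `qc`,
#'   `differential`, `top_probes`, `clustering`, `dmrs`, `pairwise_dmrs`,
#'   `longitudinal`, `summary`.
#' @export
run_pipeline <- function(cohort, config = analysis_config(), out_dir = NULL) {
  bm <- as_beta_matrix(cohort$beta)
  manifest <- validate_manifest(cohort$manifest)
  annotation <- validate_annotation(cohort$annotation)
  regions <- if (!is.null(cohort$regions)) validate_regions(cohort$regions)

  ## ---- stage 1: imprint QC -------------------------------------------
  qc <- NULL
  kept_samples <- colnames(bm$beta)
  icrs <- if (!is.null(regions))
    regions[regions$parent_of_origin != "none", , drop = FALSE]
  if (!is.null(icrs) && nrow(icrs) >= 2 && ncol(bm$beta) >= 3) {
    icr_means <- summarize_icrs(bm, annotation, icrs)
    qc <- flag_outlier_samples(icr_means, icrs, pca_z = config$pca_z,
                               alpha_flag = config$alpha_flag,
                               cv_uniformity = config$cv_uniformity,
                               alpha_verdict = config$alpha_verdict)
    kept_samples <- qc$sample_id[!qc$flagged]
  }
  bm_kept <- beta_matrix(bm$beta[, kept_samples, drop = FALSE],
                         if (!is.null(bm$coverage))
                           bm$coverage[, kept_samples, drop = FALSE])
  manifest_kept <- manifest[manifest$sample_id %in% kept_samples, , drop = FALSE]

  ## ---- stage 2: probe filter + baseline differential ------------------
  keep_probes <- filter_probes(annotation, config$maf_cutoff)
  bm_f <- beta_matrix(bm_kept$beta[keep_probes, , drop = FALSE],
                      if (!is.null(bm_kept$coverage))
                        bm_kept$coverage[keep_probes, , drop = FALSE])
  has_baseline_groups <-
    sum(tapply(manifest_kept$timepoint_months, manifest_kept$cohort,
               function(t) any(t == 0))) >= 2
  diffres <- top_probes <- clustering <- dmrs <- NULL
  pairwise <- list()
  if (has_baseline_groups) {
    diffres <- anova_per_probe(bm_f, manifest_kept,
                               alpha_sig = config$alpha_sig,
                               use_fdr = config$use_fdr)
    diffres <- tukey_posthoc(diffres, alpha_sig = config$alpha_sig)
    top_probes <- select_top_k(diffres, min(config$top_k,
                                            sum(!is.na(diffres$p))))
    if (length(top_probes) >= 3 &&
        sum(manifest_kept$timepoint_months == 0) >= 3)
      clustering <- cluster_and_purity(bm_f, top_probes, manifest_kept)

    ## ---- stage 3: DMR discovery ---------------------------------------
    sig_sites <- function(ids) {
      ann <- annotation[match(ids, annotation$probe_id), ]
      data.frame(chrom = ann$chrom, pos = ann$pos, probe_id = ann$probe_id,
                 stringsAsFactors = FALSE)
    }
    if (any(diffres$significant)) {
      dmrs <- rank_dmrs(dmr_group_means(
        merge_sites(sig_sites(diffres$probe_id[diffres$significant]),
                    config$merge_distance_bp), diffres))
    }
    for (pair in c("HD_CC", "TC_CC")) {
      scol <- paste0("sig_", pair)
      if (scol %in% names(diffres) && any(diffres[[scol]]))
        pairwise[[pair]] <- rank_dmrs(
          merge_sites(sig_sites(diffres$probe_id[diffres[[scol]]]),
                      config$merge_distance_bp))
    }
  }

  ## ---- stage 4: longitudinal dynamics ---------------------------------
  longi <- NULL
  consecutive <- !any(manifest_kept$timepoint_months == 0)
  multi <- any(tapply(manifest_kept$timepoint_months,
                      manifest_kept$subject_id, length) >= 2)
  if (multi) {
    longi <- list(report = longitudinal_report(bm_f, manifest_kept,
                                               cutoff = config$delta_beta_cutoff,
                                               consecutive = consecutive))
    tb <- longi$report$table
    if (any(tb$cohort == "CC"))
      longi$reference_mean <- tryCatch(reference_drift(longi$report),
                                       error = function(e) mean(tb$n_total[tb$cohort == "CC"]))
    if (!is.null(longi$reference_mean) && longi$reference_mean > 0)
      longi$report$table$fold_vs_reference <-
        fold_vs_reference(tb$n_total, longi$reference_mean)
    # dynamic-CpG enrichment on the capture path
    if (!is.null(bm_f$coverage)) {
      bm_cov <- filter_common_covered(bm_f, config$min_coverage,
                                      config$coverage_exclusive)
      rep_cov <- longitudinal_report(bm_cov, manifest_kept,
                                     cutoff = config$delta_beta_cutoff,
                                     consecutive = consecutive)
      cls <- classify_dynamic(rowMeans(bm_cov$beta, na.rm = TRUE),
                              config$dynamic_low, config$dynamic_high)
      longi$dynamic_pct <- vapply(rep_cov$altered, dynamic_fraction_of_changes,
                                  numeric(1), classification = cls)
      longi$capture_report <- rep_cov
      longi$n_common_covered <- nrow(bm_cov$beta)
    }
  }

  ## ---- run summary -----------------------------------------------------
  summary <- list(
    package_version = as.character(utils::packageVersion("spermethylome")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    n_samples_in = ncol(bm$beta),
    n_samples_kept = length(kept_samples),
    flagged_samples = if (!is.null(qc)) qc$sample_id[qc$flagged] else character(),
    n_probes_in = nrow(bm$beta),
    n_probes_filtered = length(keep_probes),
    n_significant = if (!is.null(diffres)) sum(diffres$significant) else NA,
    n_top = length(top_probes),
    clustering_purity = if (!is.null(clustering)) clustering$purity else NA,
    n_dmrs = if (!is.null(dmrs)) nrow(dmrs) else NA,
    n_pairwise_dmrs = lapply(pairwise, nrow),
    longitudinal_pairs = if (!is.null(longi)) nrow(longi$report$table) else 0L)
  stopifnot(is.na(summary$n_significant) ||
              summary$n_significant <= summary$n_probes_filtered)

  run <- structure(list(qc = qc, differential = diffres,
                        top_probes = top_probes, clustering = clustering,
                        dmrs = dmrs, pairwise_dmrs = pairwise,
                        longitudinal = longi, summary = summary),
                   class = "pipeline_run")
  if (!is.null(out_dir)) .write_run(run, out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("pipeline_run: %d/%d samples kept, %d probes; ",
                     "%s significant, %s DMRs, purity %s, %d longitudinal pairs\n"),
              s$n_samples_kept, s$n_samples_in, s$n_probes_filtered,
              format(s$n_significant), format(s$n_dmrs),
              format(s$clustering_purity), s$longitudinal_pairs))
  invisible(x)
}

.write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  if (!is.null(run$qc))
    data.table::fwrite(run$qc, p("qc_report.tsv"), sep = "\t", quote = FALSE)
  if (!is.null(run$differential))
    data.table::fwrite(run$differential, p("per_probe_results.tsv"),
                       sep = "\t", quote = FALSE)
  if (length(run$top_probes))
    writeLines(run$top_probes, p("top_probes.txt"))
  if (!is.null(run$dmrs))
    write_dmrs(run$dmrs, p("dmrs.bed"), p("dmrs_ranked.tsv"))
  for (pair in names(run$pairwise_dmrs))
    write_dmrs(run$pairwise_dmrs[[pair]],
               p(sprintf("dmrs_%s.bed", pair)),
               p(sprintf("dmrs_%s_ranked.tsv", pair)))
  if (!is.null(run$longitudinal))
    data.table::fwrite(run$longitudinal$report$table,
                       p("longitudinal_report.tsv"), sep = "\t", quote = FALSE)
  jsonlite::write_json(run$summary, p("run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(out_dir)
}

#' Write a simulated cohort's inputs to a directory
#'
#' Emits the beta TSV (plus coverage in capture mode), manifest CSV,
#' annotation TSV, regions BED and a JSON ground-truth file, i.e. the
#' complete file-level interface consumed by [run_pipeline()].
#'
#' @param cohort A `sperm_cohort`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_beta_matrix(cohort$beta, p("beta.tsv"),
                    if (!is.null(cohort$beta$coverage)) p("coverage.tsv"))
  write_manifest(cohort$manifest, p("manifest.csv"))
  write_annotation(cohort$annotation, p("annotation.tsv"))
  if (!is.null(cohort$regions)) write_regions(cohort$regions, p("regions.bed"))
  truth <- cohort$truth
  truth$baseline_profile <- NULL        # bulky; regenerate from the seed
  truth$dynamic <- NULL
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(out_dir)
}
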