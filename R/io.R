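# Domain containers and file I/O shared by every pipeline stage.
#
# Conventions: betas are fractions in [0,1] (percent only at presentation);
# genomic coordinates are 0-based half-open (BED); missing betas stay missing
# and are excluded pairwise downstream, never imputed.

#' Construct a beta-value matrix container
#'
#' Bundles a probes x samples matrix of methylation beta values with an
#' optional, cell-for-cell aligned coverage matrix (reads per CpG) used by
#' the capture-sequencing path.
#'
#' @param beta Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids). Values in \[0,1\] or `NA`.
#' @param coverage Optional matrix of non-negative integer read counts with
#'   identical dimnames.
#' @return An object of class `beta_matrix`: a list with elements `beta`
#'   and `coverage`.
#' @export
beta_matrix <- function(beta, coverage = NULL) {
  stopifnot(is.matrix(beta))
  if ((nrow(beta) > 0 && is.null(rownames(beta))) ||
      (ncol(beta) > 0 && is.null(colnames(beta))))
    stop("beta matrix must carry probe ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(beta)))
    stop("duplicated probe ids in beta matrix")
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(beta))
    stop(sprintf("beta value out of [0,1]: probe '%s', sample '%s' (value %g)",
                 rownames(beta)[i[1]], colnames(beta)[i[2]], beta[bad[1]]))
  }
  if (!is.null(coverage)) {
    stopifnot(is.matrix(coverage))
    if (!identical(dim(coverage), dim(beta)) ||
        !identical(dimnames(coverage), dimnames(beta)))
      stop("coverage matrix must align cell-for-cell with beta")
    if (any(coverage < 0, na.rm = TRUE)) stop("negative coverage values")
  }
  structure(list(beta = beta, coverage = coverage), class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples%s\n",
              nrow(x$beta), ncol(x$beta),
              if (is.null(x$coverage)) "" else " (with coverage)"))
  invisible(x)
}

as_beta_matrix <- function(x) {
  if (inherits(x, "beta_matrix")) return(x)
  if (is.matrix(x)) return(beta_matrix(x))
  stop("expected a beta_matrix or a probes x samples matrix")
}

#' Read a beta-value matrix from TSV
#'
#' First column `probe_id`, remaining columns one per sample. Empty cells
#' become missing values (never zero); values outside \[0,1\] are rejected.
#'
#' @param path TSV file path.
#' @param coverage_path Optional TSV of identical layout holding per-CpG
#'   read counts.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path, coverage_path = NULL) {
  beta <- .read_probe_table(path, "beta matrix")
  coverage <- if (!is.null(coverage_path)) {
    cv <- .read_probe_table(coverage_path, "coverage matrix")
    storage.mode(cv) <- "integer"
    cv
  }
  beta_matrix(beta, coverage)
}

.read_probe_table <- function(path, what) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = c("", "NA"))
  if (names(dt)[1] != "probe_id")
    stop(sprintf("%s '%s': first column must be 'probe_id'", what, path))
  for (j in setdiff(names(dt), "probe_id")) {
    col <- dt[[j]]
    if (is.character(col)) {
      bad <- which(!is.na(col) & is.na(suppressWarnings(as.numeric(col))))
      if (length(bad))
        stop(sprintf("%s '%s': non-numeric value '%s' in column '%s', line %d",
                     what, path, col[bad[1]], j, bad[1] + 1L))
      data.table::set(dt, j = j, value = as.numeric(col))
    }
  }
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- dt$probe_id
  m
}

#' Write a beta-value matrix (and optional coverage) to TSV
#'
#' @param bm A [beta_matrix()].
#' @param path Output TSV path for betas.
#' @param coverage_path Optional output path for the coverage companion.
#' @return Invisibly, `path`.
#' @export
write_beta_matrix <- function(bm, path, coverage_path = NULL) {
  bm <- as_beta_matrix(bm)
  .write_probe_table(bm$beta, path)
  if (!is.null(coverage_path)) {
    if (is.null(bm$coverage)) stop("no coverage matrix to write")
    .write_probe_table(bm$coverage, coverage_path)
  }
  invisible(path)
}

.write_probe_table <- function(m, path) {
  dt <- data.table::data.table(probe_id = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(m))
  data.table::fwrite(dt, path, sep = "\t", na = "", quote = FALSE)
}

#' Validate and normalise a sample manifest
#'
#' @param df Data frame with columns `sample_id`, `subject_id`, `cohort`
#'   (one of CC/HD/TC) and `timepoint_months` (0 = baseline). Optional
#'   per-subject metadata columns pass through untouched.
#' @return The validated data frame (cohort as character).
#' @export
validate_manifest <- function(df) {
  need <- c("sample_id", "subject_id", "cohort", "timepoint_months")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  df$cohort <- as.character(df$cohort)
  bad <- setdiff(unique(df$cohort), COHORT_LEVELS)
  if (length(bad))
    stop("unknown cohort label(s): ", paste(bad, collapse = ", "),
         " (expected CC, HD or TC)")
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in manifest")
  key <- paste(df$subject_id, df$timepoint_months)
  if (anyDuplicated(key))
    stop("duplicate (subject_id, timepoint_months) pair: ", key[duplicated(key)][1])
  if (any(df$timepoint_months < 0)) stop("negative timepoint_months")
  ncoh <- tapply(df$cohort, df$subject_id, function(x) length(unique(x)))
  if (any(ncoh > 1))
    stop("cohort differs across rows for subject(s): ",
         paste(names(ncoh)[ncoh > 1], collapse = ", "))
  no_base <- names(which(tapply(df$timepoint_months, df$subject_id, min) > 0))
  if (length(no_base))
    message("manifest: no baseline (0 months) sample for subject(s): ",
            paste(no_base, collapse = ", "))
  as.data.frame(df)
}

#' Read a sample manifest from CSV
#'
#' @param path CSV path with header `sample_id,subject_id,cohort,timepoint_months`.
#' @return Validated manifest data frame.
#' @export
read_manifest <- function(path) {
  validate_manifest(data.table::fread(path, header = TRUE, data.table = FALSE))
}

#' Write a sample manifest to CSV
#' @param manifest Manifest data frame.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(manifest, path) {
  lead <- c("sample_id", "subject_id", "cohort", "timepoint_months")
  manifest <- manifest[, c(lead, setdiff(names(manifest), lead)), drop = FALSE]
  data.table::fwrite(manifest, path, na = "", quote = FALSE)
  invisible(path)
}

REGION_COLS <- c("chrom", "start", "end", "name", "parent_of_origin",
                 "expected_sperm_beta", "expected_somatic_beta")

#' Validate a region set (ICRs and candidate loci)
#'
#' Regions are 0-based half-open intervals. ICR entries carry a
#' parent-of-origin and both the expected sperm and somatic beta levels used
#' by the contamination mixture model.
#'
#' @param df Data frame with columns `chrom`, `start`, `end`, `name`, and
#'   optionally `parent_of_origin` (`paternal`/`maternal`/`none`),
#'   `expected_sperm_beta`, `expected_somatic_beta`.
#' @return Validated data frame with all seven columns present.
#' @export
validate_regions <- function(df) {
  miss <- setdiff(c("chrom", "start", "end", "name"), names(df))
  if (length(miss)) stop("region set missing columns: ", paste(miss, collapse = ", "))
  if (!"parent_of_origin" %in% names(df)) df$parent_of_origin <- "none"
  if (!"expected_sperm_beta" %in% names(df)) df$expected_sperm_beta <- NA_real_
  if (!"expected_somatic_beta" %in% names(df)) df$expected_somatic_beta <- NA_real_
  if (any(df$start < 0)) stop("negative region start")
  if (any(df$start >= df$end))
    stop("region with start >= end: ", df$name[df$start >= df$end][1])
  bad <- setdiff(unique(df$parent_of_origin), c("paternal", "maternal", "none"))
  if (length(bad)) stop("unknown parent_of_origin: ", paste(bad, collapse = ", "))
  icr <- df$parent_of_origin != "none"
  if (any(icr & (is.na(df$expected_sperm_beta) | is.na(df$expected_somatic_beta))))
    stop("ICR regions must carry expected_sperm_beta and expected_somatic_beta")
  as.data.frame(df[, REGION_COLS])
}

#' Read a region set from a BED-like file
#'
#' BED 4+ columns without header: chrom, start, end, name, then optionally
#' parent_of_origin, expected_sperm_beta, expected_somatic_beta.
#'
#' @param path BED file path.
#' @return Validated region data frame.
#' @export
read_regions <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE,
                          na.strings = c("", ".", "NA"))
  if (ncol(df) < 4) stop("region BED needs at least 4 columns")
  names(df) <- REGION_COLS[seq_len(min(ncol(df), 7L))]
  validate_regions(df)
}

#' Write a region set to BED
#' @param regions Region data frame (see [validate_regions()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_regions <- function(regions, path) {
  regions <- validate_regions(regions)
  data.table::fwrite(regions[, REGION_COLS], path, sep = "\t",
                     col.names = FALSE, na = ".", quote = FALSE)
  invisible(path)
}

#' Validate a probe annotation table
#'
#' @param df Data frame with columns `probe_id`, `chrom`, `pos` (0-based),
#'   and optionally `strand`, `multi_mapped`, `snp_maf`.
#' @return Validated data frame with all six columns.
#' @export
validate_annotation <- function(df) {
  miss <- setdiff(c("probe_id", "chrom", "pos"), names(df))
  if (length(miss)) stop("annotation missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$probe_id))
    stop("duplicated probe_id in annotation: ", df$probe_id[duplicated(df$probe_id)][1])
  if (any(df$pos < 0)) stop("negative probe position")
  if (!"strand" %in% names(df)) df$strand <- "."
  if (!"multi_mapped" %in% names(df)) df$multi_mapped <- FALSE
  if (!"snp_maf" %in% names(df)) df$snp_maf <- NA_real_
  df$multi_mapped <- as.logical(df$multi_mapped)
  ok <- is.na(df$snp_maf) | (df$snp_maf >= 0 & df$snp_maf <= 1)
  if (!all(ok)) stop("snp_maf outside [0,1]")
  as.data.frame(df[, c("probe_id", "chrom", "pos", "strand", "multi_mapped", "snp_maf")])
}

#' Read a probe annotation table from TSV
#' @param path TSV with header (`probe_id`, `chrom`, `pos`, `strand`,
#'   `multi_mapped`, `snp_maf`).
#' @return Validated annotation data frame.
#' @export
read_annotation <- function(path) {
  validate_annotation(data.table::fread(path, sep = "\t", header = TRUE,
                                        data.table = FALSE, na.strings = c("", "NA")))
}

#' Write a probe annotation table to TSV
#' @param annotation Annotation data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(annotation, path) {
  annotation <- validate_annotation(annotation)
  data.table::fwrite(annotation, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Analysis configuration with the pipeline's thresholds
#'
#' Defaults follow the array workflow: raw p < 0.05 significance, top 500
#' probes for signature clustering, 1 kb DMR merge distance, a strict
#' delta-beta cutoff of 0.2 for longitudinal change, inclusive 0.2-0.8
#' bounds for dynamic CpGs, inclusive minimum tenfold coverage, and a
#' strictly-greater-than 1% minor-allele-frequency probe filter.
#'
#' @param alpha_sig Per-probe significance level.
#' @param top_k Number of most significant probes used for signature
#'   clustering.
#' @param merge_distance_bp Maximum gap (bp) between significant sites
#'   merged into one DMR.
#' @param delta_beta_cutoff Within-subject beta change counted as altered
#'   when strictly exceeded.
#' @param dynamic_low,dynamic_high Inclusive reference-methylation bounds
#'   classifying a CpG as dynamic.
#' @param min_coverage Minimum per-sample read coverage (inclusive) for the
#'   capture path; set `coverage_exclusive = TRUE` for a strict `>`.
#' @param maf_cutoff Probes with SNP minor allele frequency strictly above
#'   this are removed.
#' @param cv_uniformity Coefficient-of-variation threshold below which
#'   per-ICR implied contamination fractions count as uniform.
#' @param alpha_verdict Minimum estimated contamination fraction before a
#'   sample can be called contaminated / locus-anomalous.
#' @param alpha_flag Contamination fraction above which a sample is flagged
#'   for exclusion.
#' @param pca_z Robust z-score threshold on ICR principal-component scores
#'   for outlier flagging.
#' @param coverage_exclusive Use strict `>` instead of `>=` for the
#'   coverage filter.
#' @param use_fdr Apply Benjamini-Hochberg adjustment before calling
#'   per-probe significance (off by default; the default workflow uses raw
#'   p values).
#' @param rng_seed Seed for any randomised control analyses.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(alpha_sig = 0.05, top_k = 500L,
                            merge_distance_bp = 1000L, delta_beta_cutoff = 0.2,
                            dynamic_low = 0.2, dynamic_high = 0.8,
                            min_coverage = 10L, maf_cutoff = 0.01,
                            cv_uniformity = 0.5, alpha_verdict = 0.05,
                            alpha_flag = 0.1, pca_z = 6,
                            coverage_exclusive = FALSE, use_fdr = FALSE,
                            rng_seed = 1L) {
  cfg <- list(alpha_sig = alpha_sig, top_k = as.integer(top_k),
              merge_distance_bp = as.integer(merge_distance_bp),
              delta_beta_cutoff = delta_beta_cutoff,
              dynamic_low = dynamic_low, dynamic_high = dynamic_high,
              min_coverage = as.integer(min_coverage), maf_cutoff = maf_cutoff,
              cv_uniformity = cv_uniformity, alpha_verdict = alpha_verdict,
              alpha_flag = alpha_flag, pca_z = pca_z,
              coverage_exclusive = isTRUE(coverage_exclusive),
              use_fdr = isTRUE(use_fdr), rng_seed = as.integer(rng_seed))
  stopifnot(cfg$alpha_sig > 0, cfg$alpha_sig < 1,
            cfg$dynamic_low < cfg$dynamic_high,
            cfg$merge_distance_bp > 0, cfg$delta_beta_cutoff > 0,
            cfg$min_coverage > 0, cfg$maf_cutoff > 0, cfg$top_k >= 0)
  class(cfg) <- "analysis_config"
  cfg
}

#' Read an analysis configuration from YAML
#'
#' Keys are the arguments of [analysis_config()]; absent keys keep their
#' defaults, unknown keys are an error.
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(analysis_config)))
  if (length(unknown))
    stop("unknown analysis config key(s): ", paste(unknown, collapse = ", "))
  do.call(analysis_config, vals)
}
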