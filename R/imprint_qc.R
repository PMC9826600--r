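# Imprinted-region QC: ICR summarisation, somatic-contamination estimation
# and sample outlier flagging.
#
# Sperm carries near-complete methylation at paternally methylated ICRs
# (H19) and near-zero methylation at maternally methylated ICRs (MEST,
# KCNQ1OT1, SNRPN), while somatic cells sit near 50% at both; a sample
# that deviates toward 50% across ALL ICRs to a similar extent is
# contaminated with somatic cells, whereas a deviation confined to one
# locus is a locus anomaly, not contamination.

#' Per-sample mean methylation of each region
#'
#' Averages the non-missing betas of all probes whose position falls inside
#' each region (0-based half-open, so a probe exactly at `end` is
#' excluded). Regions containing no probes are reported as missing with a
#' warning rather than an error.
#'
#' @param bm A [beta_matrix()] (or plain probes x samples matrix).
#' @param annotation Probe annotation table.
#' @param regions Region set; typically the ICR entries.
#' @return Numeric matrix, regions x samples, of mean betas.
#' @export
summarize_icrs <- function(bm, annotation, regions) {
  bm <- as_beta_matrix(bm)
  regions <- validate_regions(regions)
  ann <- annotation[match(rownames(bm$beta), annotation$probe_id), ]
  if (anyNA(ann$probe_id))
    stop("annotation does not cover all probes in the beta matrix")
  out <- matrix(NA_real_, nrow(regions), ncol(bm$beta),
                dimnames = list(regions$name, colnames(bm$beta)))
  empty <- character()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    hit <- ann$chrom == r$chrom & ann$pos >= r$start & ann$pos < r$end
    if (!any(hit)) { empty <- c(empty, r$name); next }
    out[i, ] <- colMeans(bm$beta[hit, , drop = FALSE], na.rm = TRUE)
  }
  if (length(empty))
    warning("region(s) with no probes reported as missing: ",
            paste(empty, collapse = ", "))
  out
}

#' Estimate somatic contamination of one sample from its ICR means
#'
#' Models the observed ICR mean as a two-component mixture
#' `obs_i = (1 - alpha) * s_i + alpha * m_i` of the sperm expectation `s_i`
#' and the somatic expectation `m_i`, and solves the least-squares problem
#' in closed form:
#' `alpha_hat = sum((s_i - obs_i) * (s_i - m_i)) / sum((s_i - m_i)^2)`,
#' clipped to \[0,1\]. The verdict uses the uniformity of the per-ICR
#' implied alphas: contamination pulls every ICR toward the somatic level
#' by a similar fraction, so the verdict is `contaminated` only when the
#' coefficient of variation of the implied alphas falls below
#' `cv_uniformity`; a large but non-uniform deviation is a
#' `locus_anomaly`.
#'
#' @param icr_means Named numeric vector of one sample's per-ICR means
#'   (names matching `icrs$name`).
#' @param icrs Region set whose ICR entries carry both expected betas;
#'   at least two usable ICRs are required.
#' @param cv_uniformity CV threshold for the uniformity rule.
#' @param alpha_verdict Minimum `alpha_hat` before any non-clean verdict.
#' @return A list of class `contamination_estimate`: `alpha_hat`,
#'   `per_icr_deviation` (signed observed minus sperm expectation),
#'   `implied_alpha`, `deviation_cv` and `verdict`.
#' @export
estimate_contamination <- function(icr_means, icrs, cv_uniformity = 0.5,
                                   alpha_verdict = 0.05) {
  icrs <- validate_regions(icrs)
  icrs <- icrs[icrs$parent_of_origin != "none" &
                 !is.na(icrs$expected_somatic_beta), , drop = FALSE]
  icrs <- icrs[icrs$name %in% names(icr_means), , drop = FALSE]
  obs <- icr_means[icrs$name]
  keep <- !is.na(obs)
  obs <- obs[keep]; icrs <- icrs[keep, , drop = FALSE]
  if (nrow(icrs) < 2) stop("need at least 2 ICRs with observed means")
  s <- icrs$expected_sperm_beta
  m <- icrs$expected_somatic_beta
  if (all(s == m)) stop("sperm and somatic expectations identical at every ICR")
  alpha_hat <- sum((s - obs) * (s - m)) / sum((s - m)^2)
  alpha_hat <- min(max(alpha_hat, 0), 1)
  implied <- ifelse(s == m, NA_real_, (s - obs) / (s - m))
  cv <- if (mean(implied, na.rm = TRUE) != 0)
    sd(implied, na.rm = TRUE) / abs(mean(implied, na.rm = TRUE)) else Inf
  verdict <- if (alpha_hat < alpha_verdict) "clean"
  else if (is.finite(cv) && cv < cv_uniformity) "contaminated"
  else "locus_anomaly"
  structure(list(alpha_hat = alpha_hat,
                 per_icr_deviation = setNames(obs - s, icrs$name),
                 implied_alpha = setNames(implied, icrs$name),
                 deviation_cv = cv, verdict = verdict),
            class = "contamination_estimate")
}

#' @export
print.contamination_estimate <- function(x, ...) {
  cat(sprintf("contamination estimate: alpha_hat = %.3f, cv = %.2f, verdict = %s\n",
              x$alpha_hat, x$deviation_cv, x$verdict))
  invisible(x)
}

#' Flag outlier samples from the ICR-mean table
#'
#' Computes principal-component scores on the per-sample ICR means and
#' flags samples whose robust z-score (median/MAD) on PC1 or PC2 exceeds
#' `pca_z`, or whose estimated contamination fraction exceeds
#' `alpha_flag`. Flagged samples are meant to be excluded from downstream
#' analysis but are retained in outputs with their reasons.
#'
#' @param icr_means Regions x samples matrix from [summarize_icrs()].
#' @param icrs Region set with ICR expectations (for the contamination
#'   estimator).
#' @param pca_z Robust z threshold on PC1/PC2 scores.
#' @param alpha_flag Contamination threshold for flagging.
#' @param cv_uniformity,alpha_verdict Passed to [estimate_contamination()].
#' @return Data frame with one row per sample: `sample_id`, `alpha_hat`,
#'   `verdict`, `pc1_z`, `pc2_z`, `flagged`, `reason`.
#' @export
flag_outlier_samples <- function(icr_means, icrs, pca_z = 6,
                                 alpha_flag = 0.1, cv_uniformity = 0.5,
                                 alpha_verdict = 0.05) {
  icr_means <- icr_means[stats::complete.cases(icr_means), , drop = FALSE]
  if (ncol(icr_means) < 3) stop("need at least 3 samples to flag outliers")
  x <- t(icr_means)                       # samples x ICRs
  ncomp <- min(2L, ncol(x), nrow(x) - 1L)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(ncomp), drop = FALSE]
  robust_z <- function(v) {
    s <- mad(v)
    if (s == 0) return(ifelse(v == median(v), 0, Inf))
    (v - median(v)) / s
  }
  z <- apply(scores, 2, robust_z)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1, dimnames = list(NULL, colnames(scores)))
  est <- lapply(colnames(icr_means), function(s)
    estimate_contamination(icr_means[, s], icrs, cv_uniformity, alpha_verdict))
  alpha_hat <- vapply(est, `[[`, numeric(1), "alpha_hat")
  verdict <- vapply(est, `[[`, character(1), "verdict")
  pc1_z <- z[, 1]
  pc2_z <- if (ncol(z) >= 2) z[, 2] else rep(0, nrow(z))
  reasons <- mapply(function(a, v, z1, z2) {
    r <- character()
    if (a > alpha_flag && v == "contaminated") r <- c(r, "contamination")
    if (abs(z1) > pca_z) r <- c(r, "pc1_outlier")
    if (abs(z2) > pca_z) r <- c(r, "pc2_outlier")
    paste(r, collapse = ";")
  }, alpha_hat, verdict, pc1_z, pc2_z)
  data.frame(sample_id = colnames(icr_means), alpha_hat = alpha_hat,
             verdict = verdict, pc1_z = pc1_z, pc2_z = pc2_z,
             flagged = nzchar(reasons), reason = reasons,
             row.names = NULL, stringsAsFactors = FALSE)
}
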