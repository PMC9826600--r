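# Within-subject longitudinal change detection and dynamic-CpG analysis.
#
# Each follow-up sample is compared to the same subject's baseline (or, in
# capture mode where no baseline exists, to the previous follow-up); a CpG
# counts as altered when its beta change strictly exceeds the cutoff
# (default 0.2). Control-subject drift provides the reference expectation,
# treated subjects are expressed as fold over that reference, and altered
# sites are intersected across timepoints (persistence) and subjects
# (shared response). CpGs with intermediate reference methylation
# (20-80%, inclusive) are "dynamic" and their enrichment among changes is
# tested with a Yates-corrected chi-squared.

#' Count altered CpGs between two samples of one subject
#'
#' `delta = followup - baseline`; hypermethylated when `delta > cutoff`,
#' hypomethylated when `delta < -cutoff` (strict inequalities: a change of
#' exactly the cutoff does not count). Probes missing in either sample are
#' excluded.
#'
#' @param baseline,followup Named per-probe beta vectors on the same probe
#'   universe.
#' @param cutoff Beta-change cutoff (default 0.2).
#' @return List with `n_hypo`, `n_hyper`, `n_total` and `altered`
#'   (probe ids).
#' @export
delta_counts <- function(baseline, followup, cutoff = 0.2) {
  common <- intersect(names(baseline), names(followup))
  if (!length(common)) stop("baseline and follow-up share no probes")
  d <- followup[common] - baseline[common]
  d <- d[!is.na(d)]
  hyper <- names(d)[d > cutoff]
  hypo <- names(d)[d < -cutoff]
  list(n_hypo = length(hypo), n_hyper = length(hyper),
       n_total = length(hypo) + length(hyper),
       altered = c(hypo, hyper))
}

#' Per-subject longitudinal alteration report
#'
#' Applies [delta_counts()] for every subject and follow-up. By default
#' each follow-up is compared to the subject's own baseline (0 months);
#' with `consecutive = TRUE` (capture mode, where baselines are
#' unavailable) successive collection times are compared instead.
#'
#' @param bm A [beta_matrix()].
#' @param manifest Sample manifest.
#' @param cutoff Beta-change cutoff.
#' @param consecutive Compare consecutive timepoints instead of
#'   follow-up-vs-baseline.
#' @return List of class `longitudinal_report`: `table` (subject, cohort,
#'   timepoint, reference timepoint, n_hypo/n_hyper/n_total) and `altered`
#'   (named list `"subject@timepoint"` of altered probe ids).
#' @export
longitudinal_report <- function(bm, manifest, cutoff = 0.2,
                                consecutive = FALSE) {
  bm <- as_beta_matrix(bm)
  m <- manifest[manifest$sample_id %in% colnames(bm$beta), , drop = FALSE]
  rows <- list(); altered <- list()
  for (su in unique(m$subject_id)) {
    ms <- m[m$subject_id == su, , drop = FALSE]
    ms <- ms[order(ms$timepoint_months), , drop = FALSE]
    if (consecutive) {
      if (nrow(ms) < 2) next
      pairs <- cbind(seq_len(nrow(ms) - 1L), seq(2L, nrow(ms)))
    } else {
      if (!any(ms$timepoint_months == 0)) next
      b <- which(ms$timepoint_months == 0)[1]
      fu <- which(ms$timepoint_months > 0)
      if (!length(fu)) next
      pairs <- cbind(rep(b, length(fu)), fu)
    }
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      dc <- delta_counts(bm$beta[, ms$sample_id[i]],
                         bm$beta[, ms$sample_id[j]], cutoff)
      key <- paste0(su, "@", ms$timepoint_months[j])
      rows[[key]] <- data.frame(
        subject_id = su, cohort = ms$cohort[1],
        timepoint_months = ms$timepoint_months[j],
        reference_months = ms$timepoint_months[i],
        n_hypo = dc$n_hypo, n_hyper = dc$n_hyper, n_total = dc$n_total,
        stringsAsFactors = FALSE)
      altered[[key]] <- dc$altered
    }
  }
  if (!length(rows)) stop("no subject with a usable sample pair")
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 altered = altered, cutoff = cutoff,
                 consecutive = consecutive),
            class = "longitudinal_report")
}

#' @export
print.longitudinal_report <- function(x, ...) {
  cat(sprintf("longitudinal_report: %d subject x follow-up pairs (cutoff %.2g)\n",
              nrow(x$table), x$cutoff))
  print(x$table)
  invisible(x)
}

#' Control-cohort drift: mean altered count per follow-up
#'
#' Averages `n_total` over all control (CC) subject x follow-up pairs at
#' the requested months (default the 6/12/18-month window).
#'
#' @param report A [longitudinal_report()].
#' @param months Follow-up months included in the average.
#' @return Mean altered-site count (scalar).
#' @export
reference_drift <- function(report, months = c(6, 12, 18)) {
  tb <- report$table
  cc <- tb[tb$cohort == "CC" & tb$timepoint_months %in% months, , drop = FALSE]
  if (!nrow(cc)) stop("no CC follow-ups at the requested months")
  mean(cc$n_total)
}

#' Fold change of a subject's alterations over the control reference
#'
#' @param n_total Altered-site count for one subject x follow-up.
#' @param reference_mean Control drift from [reference_drift()]; must be
#'   positive.
#' @return `n_total / reference_mean`.
#' @export
fold_vs_reference <- function(n_total, reference_mean) {
  if (reference_mean <= 0) stop("reference mean must be positive")
  n_total / reference_mean
}

#' Venn cells of altered-site sets across a subject's follow-ups
#'
#' Exact counts for every membership pattern over the union, plus the
#' persistent set (sites altered at every follow-up).
#'
#' @param sets Named list (>= 2) of altered probe-id vectors.
#' @return List with `cells` (data frame: one row per non-empty membership
#'   pattern, logical column per set, `count`), `persistent` (ids in every
#'   set) and `union_size`.
#' @export
intersect_timepoints <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 sets")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (!is.matrix(member)) member <- rbind(member)
  pattern <- apply(member, 1, function(r) paste(as.integer(r), collapse = ""))
  counts <- table(pattern)
  cells <- do.call(rbind, lapply(names(counts), function(p) {
    flags <- as.logical(as.integer(strsplit(p, "")[[1]]))
    cbind(as.data.frame(rbind(setNames(flags, names(sets)))),
          count = as.integer(counts[[p]]))
  }))
  persistent <- universe[rowSums(member) == length(sets)]
  list(cells = cells, persistent = persistent,
       union_size = length(universe))
}

#' Sites altered in common across subjects at one timepoint
#'
#' @param sets Named list (>= 2) of altered probe-id vectors, one per
#'   subject.
#' @return List with `shared` (intersection) and `shared_fraction`
#'   (per subject, |shared| / |set|).
#' @export
common_across_subjects <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 subjects")
  shared <- Reduce(intersect, sets)
  frac <- vapply(sets, function(s)
    if (length(s)) length(shared) / length(s) else NA_real_, numeric(1))
  list(shared = shared, n_shared = length(shared), shared_fraction = frac)
}

#' Restrict to CpGs covered in every sample
#'
#' Keeps CpGs whose read coverage reaches `min_coverage` in all samples
#' (inclusive `>=` by default; `exclusive = TRUE` uses a strict `>`).
#'
#' @param bm A [beta_matrix()] carrying a coverage matrix.
#' @param min_coverage Coverage threshold (default 10).
#' @param exclusive Use strict `>` instead of `>=`.
#' @return The filtered [beta_matrix()] (empty, with a warning, if no CpG
#'   passes everywhere).
#' @export
filter_common_covered <- function(bm, min_coverage = 10L, exclusive = FALSE) {
  bm <- as_beta_matrix(bm)
  if (is.null(bm$coverage)) stop("beta matrix has no coverage companion")
  ok <- if (exclusive) bm$coverage > min_coverage else bm$coverage >= min_coverage
  keep <- rowSums(ok) == ncol(bm$coverage)
  if (!any(keep)) warning("no CpG commonly covered at the requested depth")
  beta_matrix(bm$beta[keep, , drop = FALSE],
              bm$coverage[keep, , drop = FALSE])
}

#' Classify CpGs as dynamic or static
#'
#' Dynamic CpGs carry intermediate reference methylation, within
#' \[`low`, `high`\] inclusive (default 20-80%); all others are static.
#' The reference is typically the mean beta over the analysed samples but
#' any external reference vector can be supplied.
#'
#' @param reference_means Named per-CpG reference mean betas.
#' @param low,high Inclusive bounds.
#' @return Data frame of class `dynamic_classification`: `probe_id`,
#'   `reference_mean_beta`, `class`.
#' @export
classify_dynamic <- function(reference_means, low = 0.2, high = 0.8) {
  stopifnot(low < high)
  cls <- ifelse(!is.na(reference_means) &
                  reference_means >= low & reference_means <= high,
                "dynamic", "static")
  structure(data.frame(probe_id = names(reference_means),
                       reference_mean_beta = unname(reference_means),
                       class = cls, stringsAsFactors = FALSE),
            class = c("dynamic_classification", "data.frame"))
}

#' Percentage of altered sites falling at dynamic CpGs
#'
#' @param altered Altered probe ids.
#' @param classification A [classify_dynamic()] result covering all
#'   altered sites.
#' @return Percent of altered sites classified dynamic (`NA`, with a
#'   message, when no site is altered).
#' @export
dynamic_fraction_of_changes <- function(altered, classification) {
  if (!length(altered)) {
    message("no altered sites; dynamic fraction undefined")
    return(NA_real_)
  }
  idx <- match(altered, classification$probe_id)
  if (anyNA(idx)) stop("classification does not cover all altered sites")
  100 * mean(classification$class[idx] == "dynamic")
}

#' Yates-corrected chi-squared on altered proportions of two groups
#'
#' Builds the 2x2 table (altered / not altered per group) and computes
#' `chi2 = N * (max(0, |ad - bc| - N/2))^2 / ((a+b)(c+d)(a+c)(b+d))`
#' with the continuity correction floored at zero (a table at or below the
#' correction gives statistic 0 and p 1, matching base R's
#' `chisq.test(correct = TRUE)`); two-sided p from the chi-squared
#' distribution with 1 df.
#'
#' @param altered_a,n_a Altered and total CpG counts in group A.
#' @param altered_b,n_b Altered and total CpG counts in group B.
#' @return List with `chi2`, `p` and the underlying `table`.
#' @export
yates_chisq <- function(altered_a, n_a, altered_b, n_b) {
  stopifnot(altered_a >= 0, altered_b >= 0,
            altered_a <= n_a, altered_b <= n_b)
  a <- as.numeric(altered_a); b <- as.numeric(n_a) - a
  c_ <- as.numeric(altered_b); d <- as.numeric(n_b) - c_
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("altered", "not_altered")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-squared undefined: zero margin in the 2x2 table")
  n <- a + b + c_ + d
  num <- max(0, abs(a * d - b * c_) - n / 2)
  chi2 <- n * num^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE), table = tab)
}
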