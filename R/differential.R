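# Baseline cross-cohort differential methylation.
#
# Per-probe classical one-way fixed-effects ANOVA across the CC/HD/TC
# cohorts, Tukey-Kramer post hoc pairwise tests (valid at the unequal
# 7/7/6 cohort sizes), raw-p significance by default (Benjamini-Hochberg
# available as an option), top-k signature selection, hierarchical
# clustering purity, and candidate-region group comparisons.

#' Filter probes on mapping quality and SNP content
#'
#' Drops probes flagged as multi-mapping and probes whose annotated SNP
#' minor allele frequency is strictly greater than `maf_cutoff` (a probe at
#' exactly the cutoff is retained). Probe order is preserved.
#'
#' @param annotation Probe annotation table.
#' @param maf_cutoff MAF threshold (default 0.01).
#' @return Character vector of retained probe ids.
#' @export
filter_probes <- function(annotation, maf_cutoff = 0.01) {
  annotation <- validate_annotation(annotation)
  drop <- annotation$multi_mapped |
    (!is.na(annotation$snp_maf) & annotation$snp_maf > maf_cutoff)
  keep <- annotation$probe_id[!drop]
  if (!length(keep)) warning("no probes retained after filtering")
  keep
}

# Select baseline sample columns for the requested cohorts, returning the
# matrix and the aligned cohort factor.
.baseline_groups <- function(bm, manifest, baseline_only = TRUE) {
  bm <- as_beta_matrix(bm)
  m <- manifest[manifest$sample_id %in% colnames(bm$beta), , drop = FALSE]
  if (baseline_only) m <- m[m$timepoint_months == 0, , drop = FALSE]
  g <- factor(m$cohort, levels = intersect(COHORT_LEVELS, unique(m$cohort)))
  list(x = bm$beta[, m$sample_id, drop = FALSE], g = g, manifest = m)
}

# Vectorised one-way ANOVA over matrix rows. Rows are centred first so the
# sum-of-squares decomposition stays accurate near machine precision.
.row_anova <- function(x, g) {
  lv <- levels(g)
  k0 <- length(lv)
  xc <- x - rowMeans(x, na.rm = TRUE)
  n_g <- sapply(lv, function(l) rowSums(!is.na(x[, g == l, drop = FALSE])))
  sum_g <- sapply(lv, function(l) rowSums(xc[, g == l, drop = FALSE], na.rm = TRUE))
  if (!is.matrix(n_g)) { n_g <- rbind(n_g); sum_g <- rbind(sum_g) }
  colnames(n_g) <- colnames(sum_g) <- lv
  mean_g <- sum_g / n_g                       # NaN where a group is empty
  N <- rowSums(n_g)
  grand <- rowSums(sum_g) / N
  dev <- mean_g - grand
  dev[n_g == 0] <- 0
  ssb <- rowSums(n_g * dev^2)
  sstot <- rowSums(xc^2, na.rm = TRUE) - N * grand^2
  ssw <- pmax(sstot - ssb, 0)
  k_eff <- rowSums(n_g > 0)
  df1 <- k_eff - 1
  df2 <- N - k_eff
  valid <- rowSums(n_g >= 2) >= 2 & df1 >= 1 & df2 >= 1
  msw <- ssw / df2
  f <- (ssb / df1) / msw
  # degenerate variance: all values equal -> F = 0, p = 1; zero
  # within-group variance with distinct means -> p = 0
  tol <- 1e-24
  zero_w <- ssw <= tol * pmax(rowSums(x^2, na.rm = TRUE), 1)
  f[zero_w & ssb <= tol] <- 0
  f[zero_w & ssb > tol] <- Inf
  f[!valid] <- NA_real_
  p <- rep(NA_real_, length(f))
  p[valid] <- pf(f[valid], df1[valid], df2[valid], lower.tail = FALSE)
  p[valid & f == 0] <- 1
  p[valid & is.infinite(f)] <- 0
  # group means on the original scale
  raw_mean <- sapply(lv, function(l) rowMeans(x[, g == l, drop = FALSE], na.rm = TRUE))
  if (!is.matrix(raw_mean)) raw_mean <- rbind(raw_mean)
  colnames(raw_mean) <- lv
  rownames(raw_mean) <- rownames(n_g) <- NULL
  list(mean_g = raw_mean, n_g = n_g, F = f, p = p, msw = msw,
       df1 = df1, df2 = df2, k = k_eff, valid = valid)
}

#' Per-probe one-way ANOVA across cohorts
#'
#' Classical fixed-effects one-way ANOVA on the beta values of each probe:
#' `F = (SSB/(k-1)) / (SSW/(N-k))`, p from the F distribution. Missing
#' betas are excluded per probe; probes left with fewer than two cohorts of
#' at least two samples are reported with missing statistics and counted in
#' the returned skip attribute.
#'
#' @param bm A [beta_matrix()] restricted (by default) to baseline samples.
#' @param manifest Sample manifest.
#' @param baseline_only Use only `timepoint_months == 0` samples.
#' @param alpha_sig Significance level for the `significant` column.
#' @param use_fdr If `TRUE`, call significance on Benjamini-Hochberg
#'   adjusted p values (also returned as `p_adj`).
#' @return A data frame of class `differential_result` with per-probe
#'   group means, `F`, `p`, degrees of freedom, the within-group mean
#'   square (`msw`, needed for Tukey), per-group sample counts and the
#'   `significant` flag. Attribute `n_skipped` counts skipped probes.
#' @export
anova_per_probe <- function(bm, manifest, baseline_only = TRUE,
                            alpha_sig = 0.05, use_fdr = FALSE) {
  bg <- .baseline_groups(bm, manifest, baseline_only)
  if (nlevels(bg$g) < 2) stop("need at least 2 cohorts with samples")
  a <- .row_anova(bg$x, bg$g)
  res <- data.frame(probe_id = rownames(bg$x), stringsAsFactors = FALSE)
  for (l in levels(bg$g)) res[[paste0("mean_", l)]] <- a$mean_g[, l]
  res$F <- a$F
  res$p <- a$p
  res$df1 <- a$df1
  res$df2 <- a$df2
  res$msw <- a$msw
  for (l in levels(bg$g)) res[[paste0("n_", l)]] <- a$n_g[, l]
  if (use_fdr) {
    res$p_adj <- stats::p.adjust(res$p, "BH")
    res$significant <- !is.na(res$p_adj) & res$p_adj < alpha_sig
  } else {
    res$significant <- !is.na(res$p) & res$p < alpha_sig
  }
  attr(res, "cohorts") <- levels(bg$g)
  attr(res, "n_skipped") <- sum(!a$valid)
  class(res) <- c("differential_result", "data.frame")
  res
}

TUKEY_PAIRS <- list(c("HD", "CC"), c("TC", "CC"), c("TC", "HD"))

#' Tukey-Kramer post hoc pairwise comparisons
#'
#' For each cohort pair present, computes the studentized-range statistic
#' `q = |mean_i - mean_j| / sqrt(MSW/2 * (1/n_i + 1/n_j))` (Tukey-Kramer,
#' reducing to Tukey HSD at equal n) and the adjusted p from the
#' studentized-range distribution with `k` groups and `N - k` degrees of
#' freedom. Signed differences follow the pair label: `diff_HD_CC` is
#' HD mean minus CC mean, so a negative value means hypomethylated in HD.
#' When `MSW` is exactly zero the adjusted p is 0 for unequal means and 1
#' for equal means (documented convention).
#'
#' @param result A `differential_result` from [anova_per_probe()].
#' @param alpha_sig Significance level for the per-pair `sig_*` flags
#'   (applied on top of the ANOVA `significant` flag, mirroring a post hoc
#'   test run after the initial screen).
#' @return `result` with `diff_*`, `p_*` and `sig_*` columns per pair.
#' @export
tukey_posthoc <- function(result, alpha_sig = 0.05) {
  stopifnot(inherits(result, "differential_result"))
  cohorts <- attr(result, "cohorts")
  k <- length(cohorts)
  for (pair in TUKEY_PAIRS) {
    if (!all(pair %in% cohorts)) next
    i <- pair[1]; j <- pair[2]
    mi <- result[[paste0("mean_", i)]]; mj <- result[[paste0("mean_", j)]]
    ni <- result[[paste0("n_", i)]]; nj <- result[[paste0("n_", j)]]
    diff <- mi - mj
    se <- sqrt(result$msw / 2 * (1 / ni + 1 / nj))
    q <- abs(diff) / se
    ok <- !is.na(result$p) & !is.na(se) & se > 0
    p <- rep(NA_real_, nrow(result))
    p[ok] <- ptukey(q[ok], nmeans = k, df = result$df2[ok], lower.tail = FALSE)
    zero <- !is.na(result$p) & !is.na(result$msw) & result$msw == 0
    p[zero] <- ifelse(diff[zero] == 0, 1, 0)
    lab <- paste0(i, "_", j)
    result[[paste0("diff_", lab)]] <- diff
    result[[paste0("p_", lab)]] <- p
    result[[paste0("sig_", lab)]] <- result$significant & !is.na(p) & p < alpha_sig
  }
  result
}

#' Hypo/hyper split of pair-significant probes
#'
#' Among probes significant for a cohort pair, counts hypo- (negative
#' signed difference) and hypermethylated sites and the percentage hypo.
#'
#' @param result A `differential_result` with Tukey columns.
#' @param pair Pair label, e.g. `"HD_CC"` (first cohort relative to
#'   second).
#' @return List with `n_hypo`, `n_hyper`, `n_total` and `pct_hypo`
#'   (percent; `NA` when no probe is significant).
#' @export
hypo_hyper_fractions <- function(result, pair = "HD_CC") {
  dcol <- paste0("diff_", pair); scol <- paste0("sig_", pair)
  if (!all(c(dcol, scol) %in% names(result)))
    stop("no Tukey results for pair ", pair)
  d <- result[[dcol]][result[[scol]] %in% TRUE]
  n_hypo <- sum(d < 0); n_hyper <- sum(d > 0)
  total <- length(d)
  list(n_hypo = n_hypo, n_hyper = n_hyper, n_total = total,
       pct_hypo = if (total > 0) 100 * n_hypo / total else NA_real_)
}

#' Select the k most significant probes
#'
#' Orders by ANOVA p ascending, breaking ties by larger F and then by
#' probe id, so the selection is deterministic under permutation of the
#' input rows.
#'
#' @param result A `differential_result`.
#' @param k Number of probes to return.
#' @return Character vector of probe ids (all available probes, with a
#'   warning, if fewer than `k` have a p value).
#' @export
select_top_k <- function(result, k) {
  ok <- !is.na(result$p)
  if (k > sum(ok)) {
    warning("fewer probes with p values (", sum(ok), ") than k = ", k)
    k <- sum(ok)
  }
  if (k == 0) return(character())
  r <- result[ok, ]
  r$probe_id[order(r$p, -r$F, r$probe_id)][seq_len(k)]
}

#' Hierarchical clustering of samples and cohort purity
#'
#' Agglomerative clustering of samples on Euclidean distance over the
#' supplied probes with average linkage, cut into `n_clusters` clusters.
#' Purity is the fraction of samples whose cohort matches the majority
#' cohort of their cluster.
#'
#' @param bm A [beta_matrix()].
#' @param probes Probe ids to cluster on.
#' @param manifest Sample manifest (defines cohort labels); restricted to
#'   baseline samples when `baseline_only`.
#' @param n_clusters Number of clusters to cut (default 3 = cohorts).
#' @param baseline_only Use only baseline samples.
#' @return List with the `hclust` object, the cluster assignment, and
#'   `purity`.
#' @export
cluster_and_purity <- function(bm, probes, manifest, n_clusters = 3L,
                               baseline_only = TRUE) {
  bg <- .baseline_groups(bm, manifest, baseline_only)
  if (ncol(bg$x) < n_clusters)
    stop("fewer samples (", ncol(bg$x), ") than clusters (", n_clusters, ")")
  missing_probes <- setdiff(probes, rownames(bg$x))
  if (length(missing_probes)) stop("probes not in beta matrix: ",
                                   missing_probes[1], " ...")
  d <- dist(t(bg$x[probes, , drop = FALSE]))
  hc <- hclust(d, method = "average")
  cl <- cutree(hc, k = n_clusters)
  cohort <- as.character(bg$g)
  majority <- tapply(cohort, cl, function(v) max(table(v)))
  purity <- sum(majority) / length(cl)
  list(hclust = hc, clusters = cl, cohort = setNames(cohort, colnames(bg$x)),
       purity = purity)
}

#' Group comparison of a region's average methylation
#'
#' Computes each sample's mean beta over the probes inside the region
#' first, then compares the per-sample means of two groups with an
#' unpaired two-sided t test (classical, pooled variance) or an exact
#' Mann-Whitney test.
#'
#' @param bm A [beta_matrix()].
#' @param annotation Probe annotation.
#' @param region Single-row region data frame (or a name matched against
#'   `regions$name` when `regions` is supplied).
#' @param manifest Sample manifest.
#' @param groups Length-2 character vector of cohorts; the difference is
#'   `groups[1]` minus `groups[2]`.
#' @param test `"t"` or `"mann_whitney"`.
#' @param timepoint Restrict to this collection time (default baseline 0);
#'   `NULL` for all samples.
#' @return List with per-group means, `difference`, `p`, the test used and
#'   the per-sample region means.
#' @export
region_summary <- function(bm, annotation, region, manifest,
                           groups = c("TC", "CC"),
                           test = c("t", "mann_whitney"), timepoint = 0) {
  test <- match.arg(test)
  bm <- as_beta_matrix(bm)
  stopifnot(length(groups) == 2)
  region <- validate_regions(region)[1, ]
  ann <- annotation[match(rownames(bm$beta), annotation$probe_id), ]
  hit <- ann$chrom == region$chrom & ann$pos >= region$start & ann$pos < region$end
  if (!any(hit)) stop("region ", region$name, " contains no probes")
  sample_means <- colMeans(bm$beta[hit, , drop = FALSE], na.rm = TRUE)
  m <- manifest[manifest$sample_id %in% names(sample_means), , drop = FALSE]
  if (!is.null(timepoint)) m <- m[m$timepoint_months %in% timepoint, , drop = FALSE]
  v1 <- sample_means[m$sample_id[m$cohort == groups[1]]]
  v2 <- sample_means[m$sample_id[m$cohort == groups[2]]]
  if (!length(v1) || !length(v2))
    stop("empty group: ", groups[which(c(length(v1), length(v2)) == 0)][1])
  diff <- mean(v1) - mean(v2)
  if (test == "t") {
    if (length(v1) < 2 || length(v2) < 2)
      stop("t test needs >= 2 samples per group; group ",
           groups[which(c(length(v1), length(v2)) < 2)][1], " has fewer")
    p <- if (sd(v1) == 0 && sd(v2) == 0) {
      if (diff == 0) 1 else 0        # degenerate zero-variance convention
    } else t.test(v1, v2, var.equal = TRUE)$p.value
  } else {
    p <- wilcox.test(v1, v2, exact = TRUE)$p.value
  }
  list(region = region$name, n_probes = sum(hit),
       group_means = setNames(c(mean(v1), mean(v2)), groups),
       difference = diff, p = p, test = test,
       sample_means = sample_means)
}
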