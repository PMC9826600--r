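# Synthetic longitudinal sperm-methylome cohorts with ground truth.
#
# The generator reproduces the statistical structure the analysis assumes:
# bimodal sperm betas (most probes near 0 or 1), a minority of
# intermediate-methylation high-variance "dynamic" CpGs, fully methylated
# paternal / unmethylated maternal ICRs, cohort-specific implanted
# signatures (TC hypomethylation of a GDF2-like promoter, HD
# hypermethylation of a SPON2-like region, shared BASP1P1-like
# hypomethylation, scattered single-CpG effects), a transient treatment
# pulse at 6 months with geometric decay and optional per-subject
# persistence, baseline technical/biological drift, and optional
# somatic-cell contamination. Capture mode additionally simulates
# over-dispersed per-CpG read coverage.

# Approximate hg19 autosome lengths (bp), used to scatter background probes.
CHROM_LENGTHS <- c(
  chr1 = 249e6, chr2 = 243e6, chr3 = 198e6, chr4 = 191e6, chr5 = 181e6,
  chr6 = 171e6, chr7 = 159e6, chr8 = 146e6, chr9 = 141e6, chr10 = 136e6,
  chr11 = 135e6, chr12 = 134e6, chr13 = 115e6, chr14 = 107e6, chr15 = 103e6,
  chr16 = 90e6, chr17 = 81e6, chr18 = 78e6, chr19 = 59e6, chr20 = 63e6,
  chr21 = 48e6, chr22 = 51e6)

#' Built-in region set: four germline ICRs and three candidate loci
#'
#' H19 (paternally methylated, expected sperm beta 0.92, somatic 0.5) and
#' the maternally methylated MEST, KCNQ1OT1 and SNRPN ICRs (sperm 0.02,
#' somatic 0.5), plus GDF2-promoter-like, SPON2-like and BASP1P1-like
#' candidate regions whose `expected_sperm_beta` is the baseline methylation
#' the generator draws their probes around.
#'
#' @return A validated region data frame (0-based half-open coordinates).
#' @export
default_regions <- function() {
  validate_regions(data.frame(
    chrom = c("chr11", "chr7", "chr11", "chr15", "chr10", "chr4", "chr13"),
    start = c(2019000L, 130130000L, 2720000L, 25200000L, 48413000L,
              1160000L, 46000000L),
    end = c(2021000L, 130132000L, 2722000L, 25202000L, 48414500L,
            1161500L, 46000800L),
    name = c("H19_ICR", "MEST_ICR", "KCNQ1OT1_ICR", "SNRPN_ICR",
             "GDF2_promoter", "SPON2_LOC100130872", "BASP1P1"),
    parent_of_origin = c("paternal", "maternal", "maternal", "maternal",
                         "none", "none", "none"),
    expected_sperm_beta = c(0.92, 0.02, 0.02, 0.02, 0.75, 0.50, 0.60),
    expected_somatic_beta = c(0.5, 0.5, 0.5, 0.5, NA, NA, NA),
    stringsAsFactors = FALSE))
}

# Probes placed inside each built-in region (< 1 kb spacing, so a fully
# significant candidate region merges into a single DMR).
REGION_N_PROBES <- c(H19_ICR = 12L, MEST_ICR = 10L, KCNQ1OT1_ICR = 10L,
                     SNRPN_ICR = 10L, GDF2_promoter = 21L,
                     SPON2_LOC100130872 = 20L, BASP1P1 = 8L)

#' Default implanted cohort signatures
#'
#' Region-level effects: a 20-percentage-point TC hypomethylation of the
#' GDF2-like promoter (21 CpGs), a 15-point HD hypermethylation of the
#' SPON2-like region (20 CpGs) and a 15-point hypomethylation of the
#' BASP1P1-like region shared by both cancer cohorts. Scattered single-CpG
#' effects (+/- 0.15 beta) are implanted at isolated intermediate-methylation
#' probes with a hypomethylation excess in both cancer cohorts (TC 250
#' hypo / 150 hyper; HD 210 hypo / 90 hyper).
#'
#' @return List of signature entries; each has `cohorts`, `effect` and
#'   either `region` (a built-in region name) or `n_sites`.
#' @export
default_signatures <- function() {
  list(
    list(region = "GDF2_promoter", cohorts = "TC", effect = -0.20),
    list(region = "SPON2_LOC100130872", cohorts = "HD", effect = 0.15),
    list(region = "BASP1P1", cohorts = c("HD", "TC"), effect = -0.15),
    list(n_sites = 250L, cohorts = "TC", effect = -0.15),
    list(n_sites = 150L, cohorts = "TC", effect = 0.15),
    list(n_sites = 210L, cohorts = "HD", effect = -0.15),
    list(n_sites = 90L, cohorts = "HD", effect = 0.15))
}

#' Simulation configuration
#'
#' Two calibrated presets. `mode = "array"` emulates a 385,553-probe
#' methylation array cohort (7 CC / 7 HD / 6 TC subjects sampled at 0, 6,
#' 12, 18 and 24 months; 14% dynamic probes; noise calibrated so an
#' untreated subject drifts past the 0.2 delta-beta cutoff at about 145
#' probes per follow-up). `mode = "capture"` emulates a
#' 1,711,875-CpG capture-sequencing panel (2 CC / 1 HD / 1 TC subjects at
#' 12 and 18 months, no baseline; 30% dynamic CpGs; noisier betas from
#' read-sampling, calibrated so about 2.3% of CpGs change per subject with
#' roughly 83% of changes at dynamic CpGs) and adds an over-dispersed
#' coverage matrix.
#'
#' @param mode `"array"` or `"capture"`.
#' @param n_per_cohort Named integer vector `c(CC=,HD=,TC=)` of subjects
#'   per cohort (zeros allowed; at least one cohort non-empty).
#' @param n_probes Total probe universe size.
#' @param timepoints_months Collection times; 0 is baseline.
#' @param dynamic_fraction Fraction of background probes given
#'   intermediate-methylation baselines (uniform on
#'   \[`dynamic_low`,`dynamic_high`\]).
#' @param dynamic_low,dynamic_high Bounds of the intermediate band.
#' @param static_noise_sd,dynamic_noise_sd Per-sample measurement noise SD
#'   (beta units) for static and dynamic probes.
#' @param longitudinal_drift_sd Extra per-follow-up within-subject drift SD.
#' @param icr_probe_jitter,region_probe_jitter SD of per-probe offsets
#'   around a region's expected beta.
#' @param regions Region set to embed (see [default_regions()]); `NULL`
#'   for none.
#' @param signature_spec Implanted cohort signatures (see
#'   [default_signatures()]); `NULL` for none.
#' @param treatment_pulse `NULL`, or a list with `magnitude` (absolute beta
#'   shift), `n_sites`, `decay` (multiplicative per follow-up after 6
#'   months), `overlap` (fraction of each treated subject's pulse sites
#'   drawn from a common pool), `persister_decay` and `n_persisters`
#'   (subjects whose pulse decays slowly, emulating alterations that
#'   persist years post-treatment).
#' @param treated_excess Capture mode only: extra between-timepoint
#'   alterations in treated (HD/TC) subjects, emulating the elevated
#'   alteration counts observed post-chemotherapy. A list with
#'   `site_fraction` (fraction of the probe universe shifted at the last
#'   timepoint), `magnitude` (absolute beta shift) and `dynamic_bias`
#'   (fraction of excess sites drawn from dynamic CpGs); `NULL` disables.
#' @param contamination_alpha Somatic contamination fraction: scalar applied
#'   to every sample or a named per-sample vector (default 0).
#' @param coverage_mu,coverage_size Negative-binomial mean and size for
#'   simulated per-CpG coverage (capture mode only).
#' @param rng_seed Integer seed; identical config and seed give identical
#'   output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(mode = c("array", "capture"),
                       n_per_cohort = NULL, n_probes = NULL,
                       timepoints_months = NULL, dynamic_fraction = NULL,
                       dynamic_low = 0.2, dynamic_high = 0.8,
                       static_noise_sd = NULL, dynamic_noise_sd = NULL,
                       longitudinal_drift_sd = 0.02,
                       icr_probe_jitter = 0.01, region_probe_jitter = 0.02,
                       regions = default_regions(),
                       signature_spec = default_signatures(),
                       treatment_pulse = list(magnitude = 0.3, n_sites = 2900L,
                                              decay = 0.15, overlap = 0.25,
                                              persister_decay = 0.9,
                                              n_persisters = 1L),
                       treated_excess = NULL,
                       contamination_alpha = 0,
                       coverage_mu = 30, coverage_size = 10,
                       rng_seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "capture" && is.null(treated_excess))
    treated_excess <- list(site_fraction = 0.0079, magnitude = 0.3,
                           dynamic_bias = 0.85)
  if (mode == "array") {
    n_per_cohort <- n_per_cohort %||% c(CC = 7L, HD = 7L, TC = 6L)
    n_probes <- n_probes %||% 385553L
    timepoints_months <- timepoints_months %||% c(0, 6, 12, 18, 24)
    dynamic_fraction <- dynamic_fraction %||% 0.14
    static_noise_sd <- static_noise_sd %||% 0.015
    dynamic_noise_sd <- dynamic_noise_sd %||% 0.045
  } else {
    n_per_cohort <- n_per_cohort %||% c(CC = 2L, HD = 1L, TC = 1L)
    n_probes <- n_probes %||% 1711875L
    timepoints_months <- timepoints_months %||% c(12, 18)
    dynamic_fraction <- dynamic_fraction %||% 0.30
    static_noise_sd <- static_noise_sd %||% 0.057
    dynamic_noise_sd <- dynamic_noise_sd %||% 0.0745
  }
  n_per_cohort <- n_per_cohort[COHORT_LEVELS]
  names(n_per_cohort) <- COHORT_LEVELS
  n_per_cohort[is.na(n_per_cohort)] <- 0L
  stopifnot(all(n_per_cohort >= 0), sum(n_per_cohort) >= 1,
            n_probes >= 1, dynamic_fraction >= 0, dynamic_fraction <= 1,
            static_noise_sd >= 0, dynamic_noise_sd >= 0,
            longitudinal_drift_sd >= 0, dynamic_low < dynamic_high)
  if (!is.null(regions)) regions <- validate_regions(regions)
  if (!is.null(signature_spec))
    for (s in signature_spec)
      stopifnot(abs(s$effect) <= 1, all(s$cohorts %in% c("HD", "TC", "CC")))
  cfg <- list(mode = mode, n_per_cohort = n_per_cohort,
              n_probes = as.integer(n_probes),
              timepoints_months = sort(timepoints_months),
              dynamic_fraction = dynamic_fraction,
              dynamic_low = dynamic_low, dynamic_high = dynamic_high,
              static_noise_sd = static_noise_sd,
              dynamic_noise_sd = dynamic_noise_sd,
              longitudinal_drift_sd = longitudinal_drift_sd,
              icr_probe_jitter = icr_probe_jitter,
              region_probe_jitter = region_probe_jitter,
              regions = regions, signature_spec = signature_spec,
              treatment_pulse = treatment_pulse,
              treated_excess = if (mode == "capture") treated_excess,
              contamination_alpha = contamination_alpha,
              coverage_mu = coverage_mu, coverage_size = coverage_size,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "sim_config"
  cfg
}

# Annotation for the embedded regions: evenly spaced probes inside each span.
.region_probes <- function(regions) {
  out <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    n <- REGION_N_PROBES[[r$name]] %||% 10L
    step <- (r$end - r$start) %/% (n + 1L)
    data.frame(probe_id = sprintf("%s_%02d", tolower(r$name), seq_len(n)),
               chrom = r$chrom, pos = r$start + step * seq_len(n),
               region = r$name, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Scatter background probes over the autosomes, avoiding the embedded
# regions; unique positions per chromosome.
.background_probes <- function(n, regions) {
  w <- CHROM_LENGTHS / sum(CHROM_LENGTHS)
  counts <- as.vector(stats::rmultinom(1, n, w))
  chunks <- vector("list", length(CHROM_LENGTHS))
  for (i in seq_along(CHROM_LENGTHS)) {
    if (counts[i] == 0) next
    chrom <- names(CHROM_LENGTHS)[i]
    pos <- sample.int(CHROM_LENGTHS[[i]] - 2e6L, counts[i]) + 1e6L
    if (!is.null(regions)) {
      rr <- regions[regions$chrom == chrom, , drop = FALSE]
      for (j in seq_len(nrow(rr)))
        pos <- pos[pos < rr$start[j] | pos >= rr$end[j]]
      while (length(pos) < counts[i]) {  # top up after exclusions
        extra <- sample.int(CHROM_LENGTHS[[i]] - 2e6L,
                            counts[i] - length(pos)) + 1e6L
        for (j in seq_len(nrow(rr)))
          extra <- extra[extra < rr$start[j] | extra >= rr$end[j]]
        pos <- unique(c(pos, extra))
      }
    }
    chunks[[i]] <- data.frame(probe_id = NA_character_, chrom = chrom,
                              pos = pos, region = NA_character_,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, chunks)
  out$probe_id <- sprintf("cg%08d", seq_len(nrow(out)))
  out
}

#' Simulate a longitudinal sperm-methylome cohort
#'
#' Draws a per-probe baseline profile (bimodal for static probes, uniform on
#' the intermediate band for dynamic probes, region probes around their
#' expected beta), implants cohort signatures and the 6-month treatment
#' pulse, then realises each sample as baseline + effects + truncated
#' Gaussian noise on the beta scale, clipped to \[0,1\]. Capture mode also
#' draws an over-dispersed coverage matrix. All randomness flows from
#' `config$rng_seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `sperm_cohort` with elements `beta`
#'   (a [beta_matrix()]), `manifest`, `annotation`, `regions` and `truth`.
#'   `truth` records the baseline profile, the per-probe dynamic flag,
#'   implanted signature sites with per-cohort effect, per-subject pulse
#'   sites and timepoint effect sizes, and per-sample contamination
#'   fractions.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$rng_seed, .simulate_impl(config))
}

.simulate_impl <- function(cfg) {
  ## ---- probe universe -------------------------------------------------
  reg_probes <- if (!is.null(cfg$regions)) .region_probes(cfg$regions)
  n_special <- if (is.null(reg_probes)) 0L else nrow(reg_probes)
  if (n_special >= cfg$n_probes)
    stop("n_probes too small for the embedded regions")
  bg <- .background_probes(cfg$n_probes - n_special, cfg$regions)
  probes <- rbind(reg_probes, bg)
  ann <- validate_annotation(probes[, c("probe_id", "chrom", "pos")])
  n <- nrow(ann)

  ## ---- baseline profile ----------------------------------------------
  mu <- numeric(n)
  is_bg <- is.na(probes$region)
  n_bg <- sum(is_bg)
  dyn_bg <- runif(n_bg) < cfg$dynamic_fraction
  mu_bg <- numeric(n_bg)
  mu_bg[dyn_bg] <- runif(sum(dyn_bg), cfg$dynamic_low, cfg$dynamic_high)
  n_stat <- sum(!dyn_bg)
  lowside <- runif(n_stat) < 0.5                # hypo vs hyper static arm
  b <- rbeta(n_stat, 2, 40)
  mu_bg[!dyn_bg] <- ifelse(lowside, b, 1 - b)
  mu[is_bg] <- mu_bg
  if (n_special) {
    ridx <- match(probes$region[!is_bg], cfg$regions$name)
    jitter_sd <- ifelse(cfg$regions$parent_of_origin[ridx] != "none",
                        cfg$icr_probe_jitter, cfg$region_probe_jitter)
    mu[!is_bg] <- clip01(cfg$regions$expected_sperm_beta[ridx] +
                           rnorm(n_special, 0, jitter_sd))
  }
  mu <- clip01(mu)
  dynamic_flag <- mu >= cfg$dynamic_low & mu <= cfg$dynamic_high
  noise_sd <- ifelse(dynamic_flag, cfg$dynamic_noise_sd, cfg$static_noise_sd)

  ## ---- cohort signatures ----------------------------------------------
  eff <- matrix(0, n, 3, dimnames = list(NULL, COHORT_LEVELS))
  sig_rows <- list()
  taken <- logical(n)  # probes already carrying a scattered signature
  if (!is.null(cfg$signature_spec)) {
    for (s in cfg$signature_spec) {
      if (!is.null(s$region)) {
        idx <- which(probes$region %in% s$region)
        if (!length(idx)) stop("signature region not embedded: ", s$region)
      } else {
        eligible <- which(is_bg & dynamic_flag & !taken &
                            mu >= 0.35 & mu <= 0.65)
        if (s$n_sites > length(eligible))
          stop("signature site count exceeds eligible probes")
        idx <- sample(eligible, s$n_sites)
        taken[idx] <- TRUE
      }
      for (co in s$cohorts) eff[idx, co] <- eff[idx, co] + s$effect
      sig_rows[[length(sig_rows) + 1L]] <-
        data.frame(probe_id = ann$probe_id[idx],
                   cohort = rep(s$cohorts, each = length(idx)),
                   effect = s$effect,
                   region = if (!is.null(s$region)) s$region else NA_character_,
                   stringsAsFactors = FALSE)
    }
  }
  signatures <- if (length(sig_rows)) do.call(rbind, sig_rows) else
    data.frame(probe_id = character(), cohort = character(),
               effect = numeric(), region = character())

  ## ---- manifest -------------------------------------------------------
  subjects <- unlist(lapply(COHORT_LEVELS, function(co)
    if (cfg$n_per_cohort[[co]] > 0)
      sprintf("%s%d", co, seq_len(cfg$n_per_cohort[[co]]))), use.names = FALSE)
  cohort_of <- sub("[0-9]+$", "", subjects)
  manifest <- do.call(rbind, lapply(seq_along(subjects), function(i)
    data.frame(sample_id = sprintf("%s_%02dm", subjects[i], cfg$timepoints_months),
               subject_id = subjects[i], cohort = cohort_of[i],
               timepoint_months = cfg$timepoints_months,
               stringsAsFactors = FALSE)))
  manifest <- validate_manifest(manifest)

  ## ---- treatment pulse sites ------------------------------------------
  pulse <- cfg$treatment_pulse
  pulse_sites <- list(); pulse_sign <- list()
  persisters <- character()
  followups <- cfg$timepoints_months[cfg$timepoints_months > 0]
  if (!is.null(pulse) && 6 %in% cfg$timepoints_months) {
    treated <- subjects[cohort_of %in% c("HD", "TC")]
    if (length(treated)) {
      hd_first <- treated[startsWith(treated, "HD")]
      persisters <- head(unique(c(hd_first, treated)), pulse$n_persisters %||% 0L)
      pool <- which(is_bg & !taken)
      if (pulse$n_sites > length(pool))
        stop("treatment pulse site count exceeds available background probes")
      n_shared <- round((pulse$overlap %||% 0) * pulse$n_sites)
      shared <- sample(pool, n_shared)
      remaining <- setdiff(pool, shared)
      for (su in treated) {
        own <- c(shared, sample(remaining, pulse$n_sites - n_shared))
        sgn <- ifelse(mu[own] > 0.7, -1,
                      ifelse(mu[own] < 0.3, 1,
                             sample(c(-1, 1), length(own), replace = TRUE)))
        pulse_sites[[su]] <- ann$probe_id[own]
        pulse_sign[[su]] <- sgn
      }
    }
  }
  ## ---- capture-mode treated excess at the last collection time --------
  excess <- cfg$treated_excess
  excess_sites <- list(); excess_sign <- list()
  last_tp <- max(cfg$timepoints_months)
  if (!is.null(excess) && length(cfg$timepoints_months) >= 2) {
    n_exc <- round(excess$site_fraction * n)
    n_dyn <- round((excess$dynamic_bias %||% 0.5) * n_exc)
    dyn_pool <- which(is_bg & dynamic_flag & !taken)
    stat_pool <- which(is_bg & !dynamic_flag & !taken)
    for (su in subjects[cohort_of %in% c("HD", "TC")]) {
      own <- c(sample(dyn_pool, min(n_dyn, length(dyn_pool))),
               sample(stat_pool, min(n_exc - n_dyn, length(stat_pool))))
      excess_sign[[su]] <- ifelse(mu[own] > 0.7, -1,
                                  ifelse(mu[own] < 0.3, 1,
                                         sample(c(-1, 1), length(own),
                                                replace = TRUE)))
      excess_sites[[su]] <- own
    }
  }

  # effect size at each follow-up index (6 months = index 1)
  pulse_decay_at <- function(subject, tp) {
    j <- match(tp, followups)
    if (is.na(j) || is.null(pulse)) return(0)
    d <- if (subject %in% persisters) (pulse$persister_decay %||% 1) else pulse$decay
    pulse$magnitude * d^(j - 1)
  }

  ## ---- realise samples ------------------------------------------------
  beta <- matrix(NA_real_, n, nrow(manifest),
                 dimnames = list(ann$probe_id, manifest$sample_id))
  drift_sd <- sqrt(noise_sd^2 + cfg$longitudinal_drift_sd^2)
  pulse_truth <- list()
  for (j in seq_len(nrow(manifest))) {
    su <- manifest$subject_id[j]; tp <- manifest$timepoint_months[j]
    v <- mu + eff[, manifest$cohort[j]]
    if (!is.null(pulse_sites[[su]]) && tp > 0) {
      mag <- pulse_decay_at(su, tp)
      if (mag > 0) {
        idx <- match(pulse_sites[[su]], ann$probe_id)
        v[idx] <- v[idx] + pulse_sign[[su]] * mag
        pulse_truth[[length(pulse_truth) + 1L]] <-
          data.frame(subject_id = su, timepoint_months = tp,
                     n_sites = length(idx), effect = mag,
                     stringsAsFactors = FALSE)
      }
    }
    if (!is.null(excess_sites[[su]]) && tp == last_tp) {
      idx <- excess_sites[[su]]
      v[idx] <- v[idx] + excess_sign[[su]] * excess$magnitude
    }
    sdv <- if (tp > 0) drift_sd else noise_sd
    beta[, j] <- clip01(v + rnorm(n, 0, sdv))
  }

  ## ---- contamination --------------------------------------------------
  alpha <- cfg$contamination_alpha
  if (length(alpha) == 1L && is.null(names(alpha)))
    alpha <- setNames(rep(alpha, nrow(manifest)), manifest$sample_id)
  alpha_full <- setNames(rep(0, nrow(manifest)), manifest$sample_id)
  alpha_full[names(alpha)] <- alpha
  if (any(alpha_full > 0)) {
    for (s in names(alpha_full)[alpha_full > 0])
      beta[, s] <- add_contamination(beta[, s], cfg$regions, ann,
                                     alpha_full[[s]], baseline = mu)
  }

  ## ---- coverage (capture mode) ----------------------------------------
  coverage <- NULL
  if (cfg$mode == "capture") {
    coverage <- matrix(rnbinom(n * nrow(manifest), mu = cfg$coverage_mu,
                               size = cfg$coverage_size),
                       n, nrow(manifest), dimnames = dimnames(beta))
    storage.mode(coverage) <- "integer"
  }

  truth <- list(baseline_profile = setNames(mu, ann$probe_id),
                dynamic = setNames(dynamic_flag, ann$probe_id),
                signatures = signatures,
                pulse_sites = pulse_sites,
                treated_excess_sites = lapply(excess_sites, function(i)
                  ann$probe_id[i]),
                pulse_effects = if (length(pulse_truth))
                  do.call(rbind, pulse_truth) else NULL,
                persisters = persisters,
                contamination_alpha = alpha_full)
  structure(list(beta = beta_matrix(beta, coverage), manifest = manifest,
                 annotation = ann, regions = cfg$regions, truth = truth,
                 config = cfg),
            class = "sperm_cohort")
}

#' @export
print.sperm_cohort <- function(x, ...) {
  cat(sprintf("sperm_cohort (%s mode): %d probes, %d samples (%d subjects), timepoints %s\n",
              x$config$mode, nrow(x$beta$beta), ncol(x$beta$beta),
              length(unique(x$manifest$subject_id)),
              paste(x$config$timepoints_months, collapse = "/")))
  invisible(x)
}

#' Mix somatic-cell signal into a sperm sample
#'
#' Replaces each beta by `(1 - alpha) * beta + alpha * beta_somatic`, where
#' the somatic expectation is the region's `expected_somatic_beta` for
#' probes inside an ICR and the probe's baseline profile elsewhere (the
#' somatic methylome is assumed to differ from sperm chiefly at the
#' imprinted regions, which is what makes contamination detectable there).
#'
#' @param betas Named per-probe beta vector for one sample.
#' @param regions Region set; entries with `parent_of_origin != "none"` and
#'   a somatic expectation define the ICRs.
#' @param annotation Probe annotation locating each probe.
#' @param alpha Contamination fraction in \[0,1\].
#' @param baseline Named baseline-profile vector used as the somatic level
#'   outside ICRs; defaults to `betas` itself (non-ICR probes unchanged).
#' @return The mixed beta vector.
#' @export
add_contamination <- function(betas, regions, annotation, alpha,
                              baseline = betas) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0,1]")
  somatic <- baseline[names(betas)]
  icrs <- regions[regions$parent_of_origin != "none" &
                    !is.na(regions$expected_somatic_beta), , drop = FALSE]
  ann <- annotation[match(names(betas), annotation$probe_id), ]
  for (i in seq_len(nrow(icrs))) {
    r <- icrs[i, ]
    hit <- which(ann$chrom == r$chrom & ann$pos >= r$start & ann$pos < r$end)
    somatic[hit] <- r$expected_somatic_beta
  }
  (1 - alpha) * betas + alpha * somatic
}
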