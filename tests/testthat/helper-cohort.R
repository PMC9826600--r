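# Shared fixtures, built in code. The small default-structure cohort is
# generated once per test run and reused read-only across test files.

small_cohort_cache <- new.env(parent = emptyenv())

# Default-structure array cohort on a reduced probe universe (signature
# regions, ICRs, pulse and noise calibration all at their defaults).
small_cohort <- function() {
  if (is.null(small_cohort_cache$co))
    small_cohort_cache$co <- simulate_cohort(sim_config(n_probes = 15000L,
                                                        rng_seed = 42L))
  small_cohort_cache$co
}

icrs_of <- function(cohort) {
  cohort$regions[cohort$regions$parent_of_origin != "none", , drop = FALSE]
}

baseline_samples <- function(cohort) {
  cohort$manifest$sample_id[cohort$manifest$timepoint_months == 0]
}

# Minimal hand-built beta matrix with explicit probe positions.
toy_beta <- function(values, probes = sprintf("p%d", seq_len(nrow(values))),
                     samples = sprintf("s%d", seq_len(ncol(values)))) {
  m <- as.matrix(values)
  dimnames(m) <- list(probes, samples)
  beta_matrix(m)
}

toy_annotation <- function(probes, chrom = "chr1",
                           pos = seq(100L, by = 1000L, length.out = length(probes))) {
  validate_annotation(data.frame(probe_id = probes, chrom = chrom, pos = pos,
                                 stringsAsFactors = FALSE))
}

toy_manifest <- function(samples, cohorts, timepoints = 0,
                         subjects = samples) {
  validate_manifest(data.frame(sample_id = samples, subject_id = subjects,
                               cohort = cohorts, timepoint_months = timepoints,
                               stringsAsFactors = FALSE))
}
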