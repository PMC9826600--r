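test_that("zero-noise, signature-free simulation reproduces the baseline profile exactly", {
  cfg <- sim_config(n_probes = 500L, n_per_cohort = c(CC = 2, HD = 1, TC = 1),
                    timepoints_months = c(0, 6),
                    static_noise_sd = 0, dynamic_noise_sd = 0,
                    longitudinal_drift_sd = 0, icr_probe_jitter = 0,
                    region_probe_jitter = 0, signature_spec = NULL,
                    treatment_pulse = NULL, rng_seed = 3L)
  co <- simulate_cohort(cfg)
  for (s in colnames(co$beta$beta))
    expect_equal(unname(co$beta$beta[, s]),
                 unname(co$truth$baseline_profile), tolerance = 0)
})

test_that("simulation is deterministic in (config, seed) and seed-sensitive", {
  cfg <- sim_config(n_probes = 2000L, n_per_cohort = c(CC = 2, HD = 1, TC = 1),
                    timepoints_months = c(0, 6),
                    signature_spec = default_signatures()[1:3],
                    treatment_pulse = NULL, rng_seed = 9L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$beta$beta, b$beta$beta)
  expect_identical(a$truth$signatures, b$truth$signatures)
  cfg2 <- cfg; cfg2$rng_seed <- 10L
  expect_false(identical(simulate_cohort(cfg2)$beta$beta, a$beta$beta))
})

test_that("baseline ICR methylation matches sperm expectations (paternal high, maternal low)", {
  co <- small_cohort()
  im <- summarize_icrs(co$beta, co$annotation, icrs_of(co))
  base <- baseline_samples(co)
  expect_true(all(im["H19_ICR", base] > 0.85))
  expect_true(mean(im[c("MEST_ICR", "KCNQ1OT1_ICR", "SNRPN_ICR"), base]) < 0.05)
})

test_that("ground truth bookkeeping matches the configured signatures", {
  co <- small_cohort()
  sig <- co$truth$signatures
  spec <- default_signatures()
  # every configured entry realised with the configured number of sites
  scattered <- sig[is.na(sig$region) & sig$cohort == "TC" & sig$effect == -0.15, ]
  expect_equal(nrow(scattered), 250L)
  gdf2 <- sig[sig$region %in% "GDF2_promoter", ]
  expect_equal(nrow(gdf2), 21L)
  expect_equal(unique(gdf2$effect), -0.20)
  expect_true(all(sig$probe_id %in% co$annotation$probe_id))
  # BASP1P1 entry fans out to both cancer cohorts
  basp <- sig[sig$region %in% "BASP1P1", ]
  expect_setequal(unique(basp$cohort), c("HD", "TC"))
})

test_that("realised probe population matches the configured structure", {
  co <- small_cohort()
  mu <- co$truth$baseline_profile
  bg <- co$annotation$probe_id[grepl("^cg", co$annotation$probe_id)]
  frac_dyn <- mean(mu[bg] > 0.2 & mu[bg] < 0.8)
  expect_lt(abs(frac_dyn - 0.14), 0.02)    # dynamic fraction ~ configured
  # dynamic probes vary more than static ones across same-size sample sets
  base <- baseline_samples(co)
  v <- apply(co$beta$beta[bg, base], 1, var)
  expect_gt(mean(v[co$truth$dynamic[bg]]), 2 * mean(v[!co$truth$dynamic[bg]]))
})

test_that("realised signature effects agree with the implanted sizes", {
  co <- small_cohort()
  base <- co$manifest[co$manifest$timepoint_months == 0, ]
  sig <- co$truth$signatures
  tc_sites <- sig$probe_id[sig$cohort == "TC" & sig$effect == -0.15 &
                             is.na(sig$region)]
  d <- rowMeans(co$beta$beta[tc_sites, base$sample_id[base$cohort == "TC"]]) -
    rowMeans(co$beta$beta[tc_sites, base$sample_id[base$cohort == "CC"]])
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - (-0.15)), 2 * se + 0.01)
})

test_that("contamination mixing follows the closed-form mixture", {
  co <- small_cohort()
  s <- baseline_samples(co)[1]
  v <- co$beta$beta[, s]
  expect_equal(add_contamination(v, co$regions, co$annotation, 0), v)

  # alpha = 1 replaces an ICR probe by the somatic expectation
  mixed1 <- add_contamination(v, co$regions, co$annotation, 1,
                              baseline = co$truth$baseline_profile)
  h19 <- co$annotation$probe_id[startsWith(co$annotation$probe_id, "h19_icr")]
  expect_equal(unname(mixed1[h19]), rep(0.5, length(h19)))

  # alpha = 0.5 on a maternal ICR probe at 0.02 with somatic 0.5 -> 0.26
  w <- v; w["mest_icr_01"] <- 0.02
  mixed <- add_contamination(w, co$regions, co$annotation, 0.5, baseline = w)
  expect_equal(unname(mixed["mest_icr_01"]), 0.26)
  expect_error(add_contamination(v, co$regions, co$annotation, 1.2), "alpha")
})

test_that("treatment pulse is acute at 6 months and decays for non-persisters", {
  co <- small_cohort()
  pe <- co$truth$pulse_effects
  expect_true(all(pe$effect[pe$timepoint_months == 6] == 0.3))
  nonpers <- setdiff(unique(pe$subject_id), co$truth$persisters)
  later <- pe[pe$subject_id %in% nonpers & pe$timepoint_months == 12, ]
  expect_true(all(later$effect < 0.05))
  pers <- pe[pe$subject_id %in% co$truth$persisters, ]
  expect_true(all(pers$effect > 0.2))      # persister stays above the cutoff
})

test_that("oversized signature requests and tiny probe universes error", {
  expect_error(simulate_cohort(sim_config(n_probes = 1000L,
    signature_spec = list(list(n_sites = 5000L, cohorts = "TC", effect = -0.1)))),
    "exceeds eligible")
  expect_error(simulate_cohort(sim_config(n_probes = 50L)), "n_probes too small")
})

test_that("capture mode attaches an aligned over-dispersed coverage matrix", {
  co <- simulate_cohort(sim_config(mode = "capture", n_probes = 5000L,
                                   rng_seed = 2L))
  expect_false(is.null(co$beta$coverage))
  expect_identical(dimnames(co$beta$coverage), dimnames(co$beta$beta))
  cv <- as.vector(co$beta$coverage)
  expect_gt(var(cv), mean(cv))             # over-dispersed counts
  expect_equal(sort(unique(co$manifest$timepoint_months)), c(12, 18))
})
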