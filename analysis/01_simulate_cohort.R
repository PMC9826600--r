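#!/usr/bin/env Rscript
# Stage 1: generate the working cohort.
#
# Simulates a longitudinal three-cohort sperm methylome (7 CC / 7 HD / 6 TC
# subjects at 0/6/12/18/24 months) with the default implanted signatures
# (TC hypomethylated GDF2-like promoter, HD hypermethylated SPON2-like
# region, shared BASP1P1-like loss, scattered single-CpG effects) and the
# 6-month treatment pulse. The probe universe is scaled to 60,000 probes so
# every later stage re-runs in seconds; the calibrated full-scale universes
# are exercised by scripts/acceptance.R. All downstream stages read the
# files written here.

suppressMessages(library(spermethylome))

out_dir <- "results/cohort"
cfg <- sim_config(mode = "array", n_probes = 60000L, rng_seed = 20260923L)
co <- simulate_cohort(cfg)
write_cohort(co, out_dir)

message(sprintf("cohort: %d probes x %d samples (%d subjects, %d timepoints)",
                nrow(co$beta$beta), ncol(co$beta$beta),
                length(unique(co$manifest$subject_id)),
                length(cfg$timepoints_months)))
message(sprintf("implanted signature sites: %d (unique probes: %d)",
                nrow(co$truth$signatures),
                length(unique(co$truth$signatures$probe_id))))
message(sprintf("treatment pulse: %d sites per treated subject, persister: %s",
                cfg$treatment_pulse$n_sites,
                paste(co$truth$persisters, collapse = ", ")))
message("inputs written under ", out_dir)
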