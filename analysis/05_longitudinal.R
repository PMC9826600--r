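#!/usr/bin/env Rscript
# Stage 5: within-subject longitudinal change.
#
# Counts probes whose beta changes by more than 0.2 between each follow-up
# and the subject's own baseline, expresses treated subjects as fold over
# the control drift (CC follow-ups at 6/12/18 months), intersects altered
# sets across a subject's timepoints (acute vs persistent response) and
# across treated subjects (shared response).

suppressMessages(library(spermethylome))

co <- list(beta = read_beta_matrix("results/cohort/beta.tsv"),
           manifest = read_manifest("results/cohort/manifest.csv"))
cfg <- analysis_config()

rep <- longitudinal_report(co$beta, co$manifest,
                           cutoff = cfg$delta_beta_cutoff)
ref <- reference_drift(rep, months = c(6, 12, 18))
tb <- rep$table
tb$fold_vs_reference <- round(fold_vs_reference(tb$n_total, ref), 2)
message(sprintf("control drift: %.1f altered probes per follow-up (6-18 months)", ref))
at6 <- tb[tb$timepoint_months == 6 & tb$cohort != "CC", ]
message(sprintf("treated subjects at 6 months: %s",
                paste(sprintf("%s %dx", at6$subject_id,
                              round(at6$fold_vs_reference)), collapse = ", ")))

# persistence within each treated subject across follow-ups
persist <- list()
for (su in unique(at6$subject_id)) {
  keys <- grep(paste0("^", su, "@"), names(rep$altered), value = TRUE)
  if (length(keys) < 2) next
  it <- intersect_timepoints(rep$altered[keys])
  persist[[su]] <- length(it$persistent)
  message(sprintf("%s: %d sites altered at every follow-up (union %d)",
                  su, length(it$persistent), it$union_size))
}

# shared acute response between the first two treated subjects
sets6 <- rep$altered[paste0(unique(at6$subject_id)[1:2], "@6")]
cs <- common_across_subjects(sets6)
message(sprintf("sites altered in both %s and %s at 6 months: %d (%.0f%% / %.0f%% of each)",
                names(sets6)[1], names(sets6)[2], cs$n_shared,
                100 * cs$shared_fraction[1], 100 * cs$shared_fraction[2]))

dir.create("results", showWarnings = FALSE)
data.table::fwrite(tb, "results/longitudinal_report.tsv", sep = "\t",
                   quote = FALSE)
jsonlite::write_json(list(reference_drift = ref, persistent_sites = persist,
                          shared_at_6m = cs$n_shared,
                          shared_fraction = as.list(cs$shared_fraction)),
                     "results/longitudinal_summary.json",
                     auto_unbox = TRUE, digits = NA)
message("wrote results/longitudinal_report.tsv and longitudinal_summary.json")
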