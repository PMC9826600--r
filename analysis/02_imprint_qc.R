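#!/usr/bin/env Rscript
# Stage 2: imprinted-region QC and contamination screening.
#
# Summarises methylation over the four germline ICRs per sample, estimates
# a somatic-contamination fraction for each from the two-component mixture
# model, and flags outliers. To exercise the detector the same way a real
# contaminated specimen would, one extra copy of a baseline sample is mixed
# 30% with somatic expectations and pushed through the same screen.

suppressMessages(library(spermethylome))

co <- list(beta = read_beta_matrix("results/cohort/beta.tsv"),
           manifest = read_manifest("results/cohort/manifest.csv"),
           annotation = read_annotation("results/cohort/annotation.tsv"),
           regions = read_regions("results/cohort/regions.bed"))
icrs <- co$regions[co$regions$parent_of_origin != "none", ]

icr_means <- summarize_icrs(co$beta, co$annotation, icrs)
base <- co$manifest$sample_id[co$manifest$timepoint_months == 0]
message(sprintf("baseline H19 ICR mean: %.1f%% (expected > 85%%)",
                100 * mean(icr_means["H19_ICR", base])))
message(sprintf("baseline maternal ICR mean: %.1f%% (expected < 5%%)",
                100 * mean(icr_means[c("MEST_ICR", "KCNQ1OT1_ICR",
                                       "SNRPN_ICR"), base])))

# spike-in: a 30% somatic mixture of the first baseline sample
spiked <- add_contamination(co$beta$beta[, base[1]], co$regions,
                            co$annotation, alpha = 0.3)
beta2 <- cbind(co$beta$beta, SPIKE_30pct = spiked)
im2 <- summarize_icrs(beta_matrix(beta2), co$annotation, icrs)
flags <- flag_outlier_samples(im2, icrs)

dir.create("results", showWarnings = FALSE)
utils::write.table(data.frame(region = rownames(icr_means),
                              round(icr_means, 4), check.names = FALSE),
                   "results/icr_means.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
utils::write.table(flags, "results/qc_flags.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

n_flag <- sum(flags$flagged)
message(sprintf("flagged %d of %d samples:", n_flag, nrow(flags)))
print(flags[flags$flagged, c("sample_id", "alpha_hat", "verdict", "reason")])
message("the spiked sample should be the only flag, with alpha_hat near 0.3")
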