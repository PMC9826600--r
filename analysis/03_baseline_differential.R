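#!/usr/bin/env Rscript
# Stage 3: baseline cross-cohort differential methylation.
#
# On pre-treatment samples only: per-probe one-way ANOVA across CC/HD/TC,
# Tukey-Kramer post hoc pairwise tests, hypo/hyper split of the
# pair-significant sites, top-500 signature selection with
# hierarchical-clustering purity, and a size-matched random-probe control
# drawn from the non-implanted background.

suppressMessages(library(spermethylome))

co <- list(beta = read_beta_matrix("results/cohort/beta.tsv"),
           manifest = read_manifest("results/cohort/manifest.csv"),
           annotation = read_annotation("results/cohort/annotation.tsv"))
truth <- jsonlite::read_json("results/cohort/truth.json", simplifyVector = TRUE)
cfg <- analysis_config()

keep <- filter_probes(co$annotation, cfg$maf_cutoff)
bm <- beta_matrix(co$beta$beta[keep, ])
res <- anova_per_probe(bm, co$manifest, alpha_sig = cfg$alpha_sig)
res <- tukey_posthoc(res, alpha_sig = cfg$alpha_sig)
message(sprintf("probes analysed: %d; ANOVA p < %.2f: %d",
                nrow(res), cfg$alpha_sig, sum(res$significant)))
for (pair in c("HD_CC", "TC_CC")) {
  hh <- hypo_hyper_fractions(res, pair)
  message(sprintf("%s: %d significant sites, %d hypo (%.1f%%)",
                  sub("_", " vs ", pair), hh$n_total, hh$n_hypo, hh$pct_hypo))
}

top <- select_top_k(res, cfg$top_k)
cl <- cluster_and_purity(bm, top, co$manifest)
message(sprintf("top-%d clustering purity: %.2f", cfg$top_k, cl$purity))

set.seed(cfg$rng_seed)
bg <- setdiff(rownames(bm$beta), unique(truth$signatures$probe_id))
rand_purity <- replicate(20, cluster_and_purity(
  bm, sample(bg, cfg$top_k), co$manifest)$purity)
message(sprintf("random same-size probe sets: mean purity %.2f (range %.2f-%.2f)",
                mean(rand_purity), min(rand_purity), max(rand_purity)))

dir.create("results", showWarnings = FALSE)
data.table::fwrite(res, "results/per_probe_results.tsv", sep = "\t",
                   quote = FALSE)
writeLines(top, "results/top_probes.txt")
jsonlite::write_json(list(top_k = cfg$top_k, purity = cl$purity,
                          random_purity_mean = mean(rand_purity),
                          random_purity = rand_purity),
                     "results/clustering_purity.json",
                     auto_unbox = TRUE, digits = NA)
message("wrote results/per_probe_results.tsv, top_probes.txt, clustering_purity.json")
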