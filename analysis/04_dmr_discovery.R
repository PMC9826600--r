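#!/usr/bin/env Rscript
# Stage 4: differentially methylated regions.
#
# Merges significant CpG sites lying within 1 kb of one another (BEDtools
# gap semantics) into DMRs, for the three-group ANOVA screen and for each
# cancer-vs-control Tukey contrast; reports the singleton percentage and
# the top regions by member-site count.

suppressMessages(library(spermethylome))

res <- data.table::fread("results/per_probe_results.tsv", data.table = FALSE)
ann <- read_annotation("results/cohort/annotation.tsv")
cfg <- analysis_config()

sites_of <- function(ids) {
  a <- ann[match(ids, ann$probe_id), ]
  data.frame(chrom = a$chrom, pos = a$pos, probe_id = a$probe_id)
}

report <- function(label, ids) {
  dmrs <- rank_dmrs(merge_sites(sites_of(ids), cfg$merge_distance_bp))
  cs <- classify_singletons(dmrs)
  message(sprintf("%s: %d sites -> %d regions; %d singletons (%.1f%%); top DMR %s:%d-%d with %d sites",
                  label, cs$total_sites, nrow(dmrs), cs$n_single,
                  cs$pct_single, dmrs$chrom[1], dmrs$start[1], dmrs$end[1],
                  dmrs$n_sites[1]))
  dmrs
}

dmrs_all <- report("three-group ANOVA", res$probe_id[res$significant])
dmrs_hd <- report("HD vs CC", res$probe_id[res$sig_HD_CC])
dmrs_tc <- report("TC vs CC", res$probe_id[res$sig_TC_CC])

multi <- function(d) sum(d$n_sites > 1)
message(sprintf("multi-site DMRs - TC: %d, HD: %d (ratio %.1f)",
                multi(dmrs_tc), multi(dmrs_hd),
                multi(dmrs_tc) / max(multi(dmrs_hd), 1)))

write_dmrs(dmrs_all, "results/dmrs_anova.bed", "results/dmrs_anova.tsv")
write_dmrs(dmrs_hd, "results/dmrs_HD_CC.bed", "results/dmrs_HD_CC.tsv")
write_dmrs(dmrs_tc, "results/dmrs_TC_CC.bed", "results/dmrs_TC_CC.tsv")
message("wrote results/dmrs_*.bed and ranked .tsv tables")
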