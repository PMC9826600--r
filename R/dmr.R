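# Merging significant CpG sites into differentially methylated regions.
#
# Each site is a 1-bp interval [pos, pos+1); adjacent intervals on the same
# chromosome merge when the gap between them (next start minus previous
# end) is at most the merge distance — BEDtools `merge -d` semantics, so
# with the default 1000 bp positions up to 1001 apart merge.

#' Merge significant sites into DMRs
#'
#' @param sites Data frame with columns `chrom`, `pos` (0-based) and
#'   optionally `probe_id`; rows must be unique sites.
#' @param merge_distance_bp Maximum gap (bp) bridged by a merge.
#' @return Data frame of regions: `chrom`, `start`, `end` (0-based
#'   half-open, covering every member site), `n_sites`, and `site_ids`
#'   (list column, sorted by position).
#' @export
merge_sites <- function(sites, merge_distance_bp = 1000L) {
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  if (any(sites$pos < 0)) stop("negative site position")
  if (!"probe_id" %in% names(sites))
    sites$probe_id <- paste0(sites$chrom, ":", sites$pos)
  if (anyDuplicated(sites[, c("chrom", "pos")]))
    stop("duplicated (chrom, pos) site")
  o <- order(sites$chrom, sites$pos)
  s <- sites[o, , drop = FALSE]
  new_chrom <- c(TRUE, s$chrom[-1] != s$chrom[-nrow(s)])
  gap <- c(Inf, s$pos[-1] - (s$pos[-nrow(s)] + 1L))
  new_region <- new_chrom | gap > merge_distance_bp
  id <- cumsum(new_region)
  dt <- data.table::data.table(chrom = s$chrom, pos = s$pos,
                               probe_id = s$probe_id, id = id)
  out <- dt[, list(chrom = chrom[1], start = min(pos), end = max(pos) + 1L,
                   n_sites = .N, site_ids = list(probe_id)), by = "id"]
  out[, "id" := NULL]
  as.data.frame(out)
}

#' Singleton/region split of merged sites
#'
#' @param dmrs Output of [merge_sites()].
#' @return List with `n_single` (regions of one site), `n_regions`
#'   (regions with 2+ sites), `total_sites` and `pct_single` (percent of
#'   all input sites that remained isolated).
#' @export
classify_singletons <- function(dmrs) {
  total <- sum(dmrs$n_sites)
  n_single <- sum(dmrs$n_sites == 1)
  list(n_single = n_single, n_regions = sum(dmrs$n_sites > 1),
       total_sites = total,
       pct_single = if (total > 0) 100 * n_single / total else NA_real_)
}

#' Rank DMRs by member-site count
#'
#' Descending number of significant sites, ties broken by genomic order
#' (chromosome, then start).
#'
#' @param dmrs Output of [merge_sites()].
#' @return `dmrs` reordered with a `rank` column.
#' @export
rank_dmrs <- function(dmrs) {
  o <- order(-dmrs$n_sites, dmrs$chrom, dmrs$start)
  out <- dmrs[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Attach per-group mean betas to DMRs
#'
#' Unweighted average, over a DMR's member probes, of the per-group probe
#' means from the differential result.
#'
#' @param dmrs Output of [merge_sites()] / [rank_dmrs()].
#' @param result A `differential_result` with `mean_*` columns.
#' @return `dmrs` with one `mean_*` column per cohort.
#' @export
dmr_group_means <- function(dmrs, result) {
  mcols <- grep("^mean_", names(result), value = TRUE)
  idx <- lapply(dmrs$site_ids, match, table = result$probe_id)
  for (mc in mcols)
    dmrs[[mc]] <- vapply(idx, function(i) mean(result[[mc]][i]), numeric(1))
  dmrs
}

#' Write DMRs as BED plus a ranked table
#'
#' @param dmrs Ranked DMR data frame.
#' @param bed_path Output BED path (chrom, start, end, name, n_sites).
#' @param tsv_path Optional ranked TSV path with site ids collapsed by
#'   comma.
#' @return Invisibly, `bed_path`.
#' @export
write_dmrs <- function(dmrs, bed_path, tsv_path = NULL) {
  bed <- data.frame(chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
                    name = sprintf("DMR_%04d", seq_len(nrow(dmrs))),
                    n_sites = dmrs$n_sites)
  data.table::fwrite(bed, bed_path, sep = "\t", col.names = FALSE, quote = FALSE)
  if (!is.null(tsv_path)) {
    flat <- dmrs
    flat$site_ids <- vapply(dmrs$site_ids, paste, character(1), collapse = ",")
    data.table::fwrite(flat, tsv_path, sep = "\t", quote = FALSE)
  }
  invisible(bed_path)
}
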