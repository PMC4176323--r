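#' Run the end-tag analysis pipeline on a tag table
#'
#' Convenience wrapper chaining the standard stages: cluster the TSS and
#' PAS tag ends on the 500-bp grid, quantify ppm, apply the >`min_ppm`
#' filter, associate clusters with gene models, assign each mate pair to
#' its TSC/PAC, and run preferred-pair selection, connected-unit detection
#' and fusion detection.
#'
#' @param pairs Pair table (ENDPAIR v1 columns, e.g. from
#'   [read_tag_pairs()] or [simulate_tags()]).
#' @param stats Library stats (`library_id`, `total_pairs`).
#' @param genes Gene-model table.
#' @param bin_size Cluster bin in bp (default 500).
#' @param min_ppm Strict cluster/unit expression threshold (default 5).
#' @param max_dist Gene-association window (default 50000).
#' @param ... Passed to [select_preferred()].
#' @return List with `tscs`, `pacs` (filtered cluster tables),
#'   `tsc_links`, `pac_links`, `pairs` (with cluster assignments),
#'   `cells` (per-gene TSC x PAC statistics with the `preferred` flag),
#'   `connected`, `fusions` and `pooled_total`.
#' @export
run_end_pipeline <- function(pairs, stats, genes, bin_size = 500,
                             min_ppm = 5, max_dist = 50000, ...) {
  libs <- sort(stats$library_id)
  lib_sizes <- stats::setNames(stats$total_pairs, stats$library_id)
  tss_tags <- data.frame(chrom = pairs$chrom5, pos = pairs$pos5,
                         strand = pairs$strand5,
                         library_id = pairs$library_id,
                         stringsAsFactors = FALSE)
  is_pas <- pairs$end3_kind == "PAS"
  pas_tags <- data.frame(chrom = pairs$chrom3[is_pas],
                         pos = pairs$pos3[is_pas],
                         strand = pairs$strand3[is_pas],
                         library_id = pairs$library_id[is_pas],
                         stringsAsFactors = FALSE)
  tscs <- filter_clusters(compute_ppm(
    cluster_tags(tss_tags, "TSC", bin_size, libraries = libs), lib_sizes),
    min_ppm)
  pacs <- filter_clusters(compute_ppm(
    cluster_tags(pas_tags, "PAC", bin_size, libraries = libs), lib_sizes),
    min_ppm)
  tsc_links <- associate_clusters(tscs, genes, max_dist)
  pac_links <- associate_clusters(pacs, genes, max_dist)
  pairs <- assign_pairs_to_clusters(pairs, tscs, pacs)
  pooled_total <- sum(lib_sizes)
  cells <- preferred_pairs(pairs, tsc_links, pac_links, pooled_total,
                           min_ppm = min_ppm, ...)
  connected <- find_connected_units(pairs, genes, tsc_links, pac_links,
                                    pooled_total, min_ppm = min_ppm)
  fusions <- detect_fusions(pairs, genes, tsc_links, pac_links,
                            pooled_total, ppm_thr = min_ppm)
  list(tscs = tscs, pacs = pacs, tsc_links = tsc_links,
       pac_links = pac_links, pairs = pairs, cells = cells,
       connected = connected, fusions = fusions,
       pooled_total = pooled_total)
}
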