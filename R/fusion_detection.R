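#' Detect candidate fusion transcripts from distant TSC-PAC pairs
#'
#' A TSC-PAC pairing whose two clusters belong to different genes that are
#' on different chromosomes, or separated by more than `dist_thr` bp on the
#' same chromosome, cannot arise from read-through transcription and is
#' reported as a candidate fusion transcript. Only supporting pairs with
#' mapping quality strictly above `mapq_thr` on both ends are counted
#' (repeat-mediated mismappings mimic fusions), and a candidate must exceed
#' `ppm_thr` pooled ppm (random chimeric ligation scatters pairs thinly
#' across gene pairs and is removed by this threshold).
#'
#' @param pairs Pair table with cluster assignments
#'   ([assign_pairs_to_clusters()]).
#' @param genes Gene-model table.
#' @param tsc_links,pac_links Link tables from [associate_clusters()].
#' @param pooled_total Total mapped pairs summed over libraries.
#' @param ppm_thr Strict pooled-ppm threshold (default 5).
#' @param dist_thr Minimum same-chromosome separation in bp, strict
#'   (default 3e6).
#' @param mapq_thr Strict mapping-quality threshold (default 37).
#' @return `data.frame` with one row per candidate gene pair: `gene5`,
#'   `gene3`, `chrom5`, `chrom3`, `n_pairs`, `ppm`, `min_mapq`, `distance`
#'   (NA for inter-chromosomal), sorted by gene ids (row-order invariant).
#' @export
detect_fusions <- function(pairs, genes, tsc_links, pac_links, pooled_total,
                           ppm_thr = 5, dist_thr = 3e6, mapq_thr = 37) {
  empty <- data.frame(gene5 = character(0), gene3 = character(0),
                      chrom5 = character(0), chrom3 = character(0),
                      n_pairs = integer(0), ppm = numeric(0),
                      min_mapq = integer(0), distance = integer(0))
  g5 <- cluster_gene_map(tsc_links)
  g3 <- cluster_gene_map(pac_links)
  ok <- pairs$mapq5 > mapq_thr & pairs$mapq3 > mapq_thr &
    !is.na(pairs$tsc_id) & !is.na(pairs$pac_id) &
    pairs$tsc_id %in% names(g5) & pairs$pac_id %in% names(g3)
  if (!any(ok)) return(empty)
  dt <- data.table::data.table(
    gene5 = g5[pairs$tsc_id[ok]],
    gene3 = g3[pairs$pac_id[ok]],
    mapq = pmin(pairs$mapq5[ok], pairs$mapq3[ok])
  )
  dt <- dt[gene5 != gene3]
  if (nrow(dt) == 0L) return(empty)
  dt <- dt[, .(n_pairs = .N, min_mapq = min(mapq)), by = .(gene5, gene3)]
  gi5 <- match(dt$gene5, genes$gene_id)
  gi3 <- match(dt$gene3, genes$gene_id)
  inter <- genes$chrom[gi5] != genes$chrom[gi3]
  dist <- ifelse(inter, NA_integer_,
                 .interval_gap(genes$tx_start[gi5], genes$tx_end[gi5],
                               genes$tx_start[gi3], genes$tx_end[gi3]))
  ppm <- dt$n_pairs * 1e6 / pooled_total
  keep <- (inter | dist > dist_thr) & ppm > ppm_thr
  out <- data.frame(gene5 = dt$gene5, gene3 = dt$gene3,
                    chrom5 = genes$chrom[gi5], chrom3 = genes$chrom[gi3],
                    n_pairs = dt$n_pairs, ppm = ppm,
                    min_mapq = as.integer(dt$min_mapq),
                    distance = as.integer(dist),
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out <- out[order(out$gene5, out$gene3), , drop = FALSE]
  rownames(out) <- NULL
  out
}
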