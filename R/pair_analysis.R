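#' Assign mate-pair tag ends to clusters
#'
#' Maps the 5' end of every pair to its TSC bin and the 3' end (PAS tags
#' only) to its PAC bin, using the fixed grid the clusters were built on.
#' Ends falling outside any retained cluster get `NA`.
#'
#' @param pairs Pair table (see [read_tag_pairs()]).
#' @param tscs,pacs Cluster tables from [cluster_tags()] (optionally
#'   filtered).
#' @return `pairs` with `tsc_id` and `pac_id` columns added.
#' @export
assign_pairs_to_clusters <- function(pairs, tscs, pacs) {
  w5 <- attr(tscs, "bin_size") %||% 500L
  w3 <- attr(pacs, "bin_size") %||% 500L
  k5 <- .cluster_key(pairs$chrom5, pairs$strand5, pairs$pos5, w5)
  pairs$tsc_id <- tscs$cluster_id[match(k5, .cluster_key(
    tscs$chrom, tscs$strand, tscs$rep_pos, w5))]
  k3 <- .cluster_key(pairs$chrom3, pairs$strand3, pairs$pos3, w3)
  pac_id <- pacs$cluster_id[match(k3, .cluster_key(
    pacs$chrom, pacs$strand, pacs$rep_pos, w3))]
  pac_id[pairs$end3_kind != "PAS"] <- NA_character_
  pairs$pac_id <- pac_id
  pairs
}

#' Cross-tabulate TSC x PAC pair counts within one gene
#'
#' Counts, pooled over libraries, how often each TSC of a gene is joined to
#' each PAC of the same gene by a single cDNA. Only clusters linked
#' (non-excluded) to the gene contribute.
#'
#' @param pairs Pair table with `tsc_id`/`pac_id` (see
#'   [assign_pairs_to_clusters()]).
#' @param tsc_links,pac_links Link tables from [associate_clusters()].
#' @param gene_id The gene to tabulate.
#' @param cells Optional precomputed cell counts from an earlier
#'   aggregation of the same pair table (internal fast path used when
#'   tabulating many genes).
#' @return An object of class `pair_matrix`: a list with `gene_id`, `o`
#'   (count matrix, rows = TSCs, cols = PACs), `T_i`, `P_j` (marginals) and
#'   `N` (grand total). Empty matrix when the gene has no linked clusters.
#' @export
build_pair_matrix <- function(pairs, tsc_links, pac_links, gene_id,
                              cells = NULL) {
  tsc_ids <- sort(unique(tsc_links$cluster_id[
    tsc_links$gene_id == gene_id & !tsc_links$excluded]))
  pac_ids <- sort(unique(pac_links$cluster_id[
    pac_links$gene_id == gene_id & !pac_links$excluded]))
  o <- matrix(0L, length(tsc_ids), length(pac_ids),
              dimnames = list(tsc_ids, pac_ids))
  cells <- cells %||% .pair_cell_counts(pairs)
  keep <- cells$tsc_id %in% tsc_ids & cells$pac_id %in% pac_ids
  if (any(keep)) {
    o[cbind(match(cells$tsc_id[keep], tsc_ids),
            match(cells$pac_id[keep], pac_ids))] <- cells$n[keep]
  }
  structure(list(gene_id = gene_id, o = o,
                 T_i = rowSums(o), P_j = colSums(o), N = sum(o)),
            class = "pair_matrix")
}

# one-pass aggregation of assigned pairs into (tsc_id, pac_id) counts
.pair_cell_counts <- function(pairs) {
  ok <- !is.na(pairs$tsc_id) & !is.na(pairs$pac_id)
  if (!any(ok)) {
    return(data.frame(tsc_id = character(0), pac_id = character(0),
                      n = integer(0)))
  }
  dt <- data.table::data.table(tsc_id = pairs$tsc_id[ok],
                               pac_id = pairs$pac_id[ok])
  as.data.frame(dt[, .N, by = .(tsc_id, pac_id)][, .(tsc_id, pac_id,
                                                     n = N)])
}

#' Poisson test of TSC-PAC pairing against independent end selection
#'
#' Under random (independent) selection of start and end, the expected
#' count of cell (i, j) is `e_ij = T_i * P_j / N`; the observed count is
#' compared to a Poisson with that mean and the upper tail
#' `P(X >= o_ij)` reported. A gene with a single TSC and a single PAC has
#' no alternative pairing, so its only cell gets p = 1 by convention.
#'
#' Estimating the expectation from the observed marginals makes the test
#' conservative under the null (the usual degrees-of-freedom loss of a
#' contingency table); when the expectation is known from elsewhere (a
#' generative model, a pooled reference) it can be supplied via `expected`
#' and the tail probability is then exactly calibrated.
#'
#' @param m A `pair_matrix` from [build_pair_matrix()].
#' @param expected Optional matrix of expected counts with the dimensions
#'   of `m$o`; defaults to the marginal estimate `T_i * P_j / N`.
#' @return `data.frame` with one row per cell: `gene_id`, `tsc_id`,
#'   `pac_id`, `o`, `e`, `p_value`.
#' @export
pair_independence_pvalue <- function(m, expected = NULL) {
  stopifnot(inherits(m, "pair_matrix"))
  if (length(m$o) == 0L) {
    return(data.frame(gene_id = character(0), tsc_id = character(0),
                      pac_id = character(0), o = integer(0), e = numeric(0),
                      p_value = numeric(0)))
  }
  if (m$N == 0L) stop("pair matrix has no counts (N = 0)")
  idx <- which(m$o >= 0L, arr.ind = TRUE)
  e <- if (is.null(expected)) {
    m$T_i[idx[, 1]] * m$P_j[idx[, 2]] / m$N
  } else {
    stopifnot(identical(dim(expected), dim(m$o)))
    expected[idx]
  }
  o <- m$o[idx]
  p <- stats::ppois(o - 1, e, lower.tail = FALSE)
  if (nrow(m$o) == 1L && ncol(m$o) == 1L) p[] <- 1
  data.frame(gene_id = m$gene_id,
             tsc_id = rownames(m$o)[idx[, 1]],
             pac_id = colnames(m$o)[idx[, 2]],
             o = o, e = unname(e), p_value = unname(p),
             stringsAsFactors = FALSE)
}

#' Select mutually preferred TSC-PAC pairs
#'
#' A cell is `preferred` when all of the following hold: (a) its pooled
#' expression exceeds `min_ppm` ppm and its pooled count exceeds `min_tags`
#' (both strict); (b) the independence test gives p < `alpha`; (c) the cell
#' is the strict maximum of both its row and its column (the TSC and the
#' PAC mutually select each other; ties disqualify); (d) the cell carries
#' more than `min_share` of the total tags of its TSC or of its PAC.
#'
#' @param m A `pair_matrix`.
#' @param pooled_total Total mapped pairs summed over libraries (the ppm
#'   denominator).
#' @param min_ppm,min_tags,alpha,min_share Selection thresholds (defaults
#'   5 ppm, 10 tags, 0.05, 0.5).
#' @return The cell table of [pair_independence_pvalue()] with `ppm`,
#'   `share` and `preferred` columns added.
#' @export
select_preferred <- function(m, pooled_total, min_ppm = 5, min_tags = 10,
                             alpha = 0.05, min_share = 0.5) {
  cells <- pair_independence_pvalue(m)
  if (nrow(cells) == 0L) {
    cells$ppm <- numeric(0); cells$share <- numeric(0)
    cells$preferred <- logical(0)
    return(cells)
  }
  cells$ppm <- cells$o * 1e6 / pooled_total
  ri <- match(cells$tsc_id, rownames(m$o))
  ci <- match(cells$pac_id, colnames(m$o))
  row_max <- apply(m$o, 1L, max)
  col_max <- apply(m$o, 2L, max)
  row_nmax <- apply(m$o, 1L, function(x) sum(x == max(x)))
  col_nmax <- apply(m$o, 2L, function(x) sum(x == max(x)))
  mutual <- cells$o == row_max[ri] & row_nmax[ri] == 1L &
    cells$o == col_max[ci] & col_nmax[ci] == 1L
  share_row <- ifelse(m$T_i[ri] > 0, cells$o / m$T_i[ri], 0)
  share_col <- ifelse(m$P_j[ci] > 0, cells$o / m$P_j[ci], 0)
  cells$share <- pmax(share_row, share_col)
  cells$preferred <- cells$ppm > min_ppm & cells$o > min_tags &
    cells$p_value < alpha & mutual & cells$share > min_share
  cells
}

#' Preferred-pair selection over all genes
#'
#' Convenience wrapper running [build_pair_matrix()] and
#' [select_preferred()] for every gene with linked clusters.
#'
#' @param pairs Pair table with cluster assignments.
#' @param tsc_links,pac_links Link tables from [associate_clusters()].
#' @param pooled_total Total mapped pairs over all libraries.
#' @param ... Passed to [select_preferred()].
#' @return Combined cell table over genes.
#' @export
preferred_pairs <- function(pairs, tsc_links, pac_links, pooled_total, ...) {
  genes <- sort(unique(intersect(
    tsc_links$gene_id[!tsc_links$excluded],
    pac_links$gene_id[!pac_links$excluded])))
  cells <- .pair_cell_counts(pairs)
  out <- lapply(genes, function(g) {
    m <- build_pair_matrix(pairs, tsc_links, pac_links, g, cells = cells)
    if (m$N == 0L) return(NULL)
    select_preferred(m, pooled_total, ...)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- select_preferred(
      structure(list(gene_id = NA, o = matrix(0L, 0, 0), T_i = integer(0),
                     P_j = integer(0), N = 0L), class = "pair_matrix"), 1)
  }
  rownames(out) <- NULL
  out
}

#' Overlap fraction between two transcript units
#'
#' The unit span runs from the representative TSS to the representative
#' cleavage base, oriented genomically. The overlap fraction is the Jaccard
#' index |a and b| / |a or b| by default; `method = "shorter"` divides the
#' intersection by the shorter span instead.
#'
#' @param span_a,span_b Integer pairs `c(start, end)` (0-based half-open).
#' @param method `"jaccard"` (default) or `"shorter"`.
#' @return Fraction in `[0, 1]`.
#' @export
unit_overlap_fraction <- function(span_a, span_b,
                                  method = c("jaccard", "shorter")) {
  method <- match.arg(method)
  la <- span_a[2] - span_a[1]; lb <- span_b[2] - span_b[1]
  if (la <= 0 || lb <= 0) stop("degenerate zero-length unit span")
  inter <- max(0, min(span_a[2], span_b[2]) - max(span_a[1], span_b[1]))
  denom <- if (method == "jaccard") la + lb - inter else min(la, lb)
  inter / denom
}

#' Tissue-specificity Z-scores of a transcript unit
#'
#' Standardises the unit's expression across libraries:
#' `z = (x - mu) / sigma` with `x = log2(ppm + pseudocount)`, `mu` the mean
#' and `sigma` the population standard deviation of `x`. When expression is
#' constant (`sigma = 0`) all z are defined as 0.
#'
#' @param ppm Named numeric vector of ppm per library (>= 2 libraries).
#' @param pseudocount Added before the log (default 1 ppm), so zeros are
#'   finite and the mean-0/sd-1 identities are exact.
#' @return A list with `x`, `mu`, `sigma`, `z` (named as `ppm`).
#' @export
tissue_zscores <- function(ppm, pseudocount = 1) {
  if (length(ppm) < 2L) stop("need >= 2 libraries")
  x <- log2(ppm + pseudocount)
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  z <- if (sigma > 0) (x - mu) / sigma else x * 0
  list(x = x, mu = mu, sigma = sigma, z = z)
}

#' Tissue pairs between which two units switch expression
#'
#' Reports ordered tissue pairs (t1, t2), t1 != t2, where unit A is
#' tissue-specific in t1 (z > `z_cut`) and unit B in t2.
#'
#' @param zA,zB Z-score objects from [tissue_zscores()] over the same
#'   libraries.
#' @param z_cut Z threshold (default 2).
#' @return `data.frame` with `tissue_a`, `tissue_b`.
#' @export
detect_switching_pairs <- function(zA, zB, z_cut = 2) {
  stopifnot(identical(names(zA$z), names(zB$z)))
  ta <- names(zA$z)[zA$z > z_cut]
  tb <- names(zB$z)[zB$z > z_cut]
  if (length(ta) == 0L || length(tb) == 0L) {
    return(data.frame(tissue_a = character(0), tissue_b = character(0)))
  }
  g <- data.frame(tissue_a = rep(ta, times = length(tb)),
                  tissue_b = rep(tb, each = length(ta)),
                  stringsAsFactors = FALSE)
  g <- g[g$tissue_a != g$tissue_b, , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Transcript units connecting adjacent genes
#'
#' Finds TSC-PAC pairings whose TSC belongs to one gene and whose PAC
#' belongs to a different gene on the same chromosome and strand, with the
#' gap between the upstream gene's 3'-end and the downstream gene's 5'-end
#' below `max_gap` (pairs at or beyond `max_gap`, or inter-chromosomal, are
#' fusion territory, not read-through). Only pairings exceeding `min_ppm`
#' pooled ppm are reported.
#'
#' @param pairs Pair table with cluster assignments.
#' @param genes Gene-model table.
#' @param tsc_links,pac_links Link tables.
#' @param pooled_total Total mapped pairs over libraries.
#' @param min_ppm Strict pooled-ppm threshold (default 5).
#' @param max_gap Maximum gene gap in bp (default 3e6).
#' @return `data.frame` with `tsc_id`, `pac_id`, `gene5`, `gene3`,
#'   `n_pairs`, `ppm`, `gap`.
#' @export
find_connected_units <- function(pairs, genes, tsc_links, pac_links,
                                 pooled_total, min_ppm = 5,
                                 max_gap = 3e6) {
  empty <- data.frame(tsc_id = character(0), pac_id = character(0),
                      gene5 = character(0), gene3 = character(0),
                      n_pairs = integer(0), ppm = numeric(0),
                      gap = integer(0))
  g5 <- cluster_gene_map(tsc_links)
  g3 <- cluster_gene_map(pac_links)
  ok <- !is.na(pairs$tsc_id) & !is.na(pairs$pac_id) &
    pairs$tsc_id %in% names(g5) & pairs$pac_id %in% names(g3)
  if (!any(ok)) return(empty)
  dt <- data.table::data.table(tsc_id = pairs$tsc_id[ok],
                               pac_id = pairs$pac_id[ok])
  dt <- dt[, .N, by = .(tsc_id, pac_id)]
  dt[, `:=`(gene5 = g5[tsc_id], gene3 = g3[pac_id])]
  dt <- dt[gene5 != gene3]
  if (nrow(dt) == 0L) return(empty)
  gi5 <- match(dt$gene5, genes$gene_id)
  gi3 <- match(dt$gene3, genes$gene_id)
  same <- genes$chrom[gi5] == genes$chrom[gi3] &
    genes$strand[gi5] == genes$strand[gi3]
  gap <- .interval_gap(genes$tx_start[gi5], genes$tx_end[gi5],
                       genes$tx_start[gi3], genes$tx_end[gi3])
  ppm <- dt$N * 1e6 / pooled_total
  keep <- same & gap < max_gap & ppm > min_ppm
  out <- data.frame(tsc_id = dt$tsc_id, pac_id = dt$pac_id,
                    gene5 = dt$gene5, gene3 = dt$gene3,
                    n_pairs = dt$N, ppm = ppm, gap = as.integer(gap),
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out <- out[order(out$gene5, out$gene3, out$tsc_id, out$pac_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric gene-set enrichment
#'
#' Tests each term for over-representation in the foreground relative to
#' the background with the hypergeometric upper tail `P(X >= k)`. Terms
#' with fewer than `size_min` or more than `size_max` background genes are
#' skipped (too tight or too loose to be informative).
#'
#' @param foreground Character vector of foreground gene ids (must be a
#'   subset of `background`).
#' @param background Character vector of background gene ids.
#' @param term2gene `data.frame` with columns `term` and `gene`.
#' @param size_min,size_max Term-size window in background genes (defaults
#'   100 and 500).
#' @return `data.frame` with `term`, `k` (foreground hits), `K` (term genes
#'   in background), `n` (foreground size), `N_bg`, `p_value` and a
#'   Benjamini-Hochberg `fdr` column, sorted by p.
#' @export
geneset_enrichment <- function(foreground, background, term2gene,
                               size_min = 100, size_max = 500) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (!all(foreground %in% background)) {
    stop("foreground must be a subset of background")
  }
  t2g <- term2gene[term2gene$gene %in% background, , drop = FALSE]
  t2g <- unique(t2g[, c("term", "gene")])
  sizes <- table(t2g$term)
  terms <- names(sizes)[sizes >= size_min & sizes <= size_max]
  n <- length(foreground)
  N_bg <- length(background)
  rows <- lapply(terms, function(tm) {
    members <- t2g$gene[t2g$term == tm]
    K <- length(members)
    k <- sum(foreground %in% members)
    p <- stats::phyper(k - 1, K, N_bg - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n = n, N_bg = N_bg, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(term = character(0), k = integer(0), K = integer(0),
               n = integer(0), N_bg = integer(0), p_value = numeric(0))
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
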