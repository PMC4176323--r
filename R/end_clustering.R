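#' Cluster transcript-end tags into fixed 500-bp bins
#'
#' TSS and PAS tags are clustered independently on a fixed genomic grid of
#' `bin_size`-bp bins per chromosome and strand: tag position `p` falls in
#' bin `[floor(p/w)*w, floor(p/w)*w + w)`. The grid is deterministic and
#' order-independent; a consequence (recorded as a limitation) is that a
#' tight tag cloud straddling a grid boundary becomes two clusters.
#'
#' @param tags A `data.frame` with columns `chrom`, `pos`, `strand`,
#'   `library_id` (one row per tag end).
#' @param kind `"TSC"` for TSS tags or `"PAC"` for PAS tags; only labels the
#'   output.
#' @param bin_size Bin width in bp (default 500).
#' @param libraries Optional character vector fixing the library columns of
#'   the count matrix (defaults to the libraries present, sorted).
#' @return A `data.frame` of clusters with columns `cluster_id`, `kind`,
#'   `chrom`, `strand`, `start`, `end`, `rep_pos` (the modal tag position in
#'   the bin, ties broken by the smallest coordinate), `n_tags`, and a
#'   matrix column `counts` (clusters x libraries). Attributes `bin_size`
#'   and `kind` are set.
#' @examples
#' tags <- data.frame(chrom = "chr1", pos = c(100L, 120L, 480L, 700L),
#'                    strand = "+", library_id = "brain")
#' cluster_tags(tags, "TSC")
#' @export
cluster_tags <- function(tags, kind = c("TSC", "PAC"), bin_size = 500,
                         libraries = NULL) {
  kind <- match.arg(kind)
  bin_size <- as.integer(bin_size)
  stopifnot(bin_size > 0L)
  libraries <- libraries %||% sort(unique(tags$library_id))
  if (nrow(tags) == 0L) {
    out <- data.frame(cluster_id = character(0), kind = character(0),
                      chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      rep_pos = integer(0), n_tags = integer(0))
    out$counts <- matrix(0L, 0, length(libraries),
                         dimnames = list(NULL, libraries))
    attr(out, "bin_size") <- bin_size
    attr(out, "kind") <- kind
    return(out)
  }
  dt <- data.table::data.table(chrom = tags$chrom, strand = tags$strand,
                               pos = as.integer(tags$pos),
                               library_id = tags$library_id)
  dt[, bin := pos %/% bin_size]
  meta <- dt[, .N, by = .(chrom, strand, bin, pos)]
  data.table::setorder(meta, chrom, strand, bin, -N, pos)
  rep_dt <- meta[!duplicated(paste(chrom, strand, bin))]
  data.table::setorder(rep_dt, chrom, strand, bin)
  cnt <- dt[, .N, by = .(chrom, strand, bin, library_id)]
  key <- function(d) paste(d$chrom, d$strand, d$bin, sep = ":")
  clusters <- data.frame(
    cluster_id = paste(kind, rep_dt$chrom, rep_dt$strand, rep_dt$bin,
                       sep = ":"),
    kind = kind,
    chrom = rep_dt$chrom,
    strand = rep_dt$strand,
    start = rep_dt$bin * bin_size,
    end = rep_dt$bin * bin_size + bin_size,
    rep_pos = rep_dt$pos,
    stringsAsFactors = FALSE
  )
  counts <- matrix(0L, nrow(clusters), length(libraries),
                   dimnames = list(NULL, libraries))
  ri <- match(key(cnt), key(rep_dt))
  ci <- match(cnt$library_id, libraries)
  if (anyNA(ci)) stop("tags from libraries not in `libraries`")
  counts[cbind(ri, ci)] <- cnt$N
  clusters$n_tags <- as.integer(rowSums(counts))
  clusters$counts <- counts
  attr(clusters, "bin_size") <- bin_size
  attr(clusters, "kind") <- kind
  clusters
}

#' Expression of clusters in parts per million tags (ppm)
#'
#' ppm of a cluster in a library is its tag count times 1e6 divided by the
#' library's total mapped pairs, the normalisation used for all expression
#' thresholds in the pipeline.
#'
#' @param clusters Cluster table from [cluster_tags()].
#' @param lib_sizes Named numeric vector of total mapped pairs per library,
#'   or the `stats` data.frame from [read_tag_pairs()].
#' @return The cluster table with a `ppm` matrix column added.
#' @export
compute_ppm <- function(clusters, lib_sizes) {
  if (is.data.frame(lib_sizes)) {
    lib_sizes <- stats::setNames(lib_sizes$total_pairs, lib_sizes$library_id)
  }
  libs <- colnames(clusters$counts)
  if (!all(libs %in% names(lib_sizes))) {
    stop("unknown library_id: ",
         paste(setdiff(libs, names(lib_sizes)), collapse = ", "))
  }
  tot <- lib_sizes[libs]
  if (any(tot <= 0)) stop("library totals must be positive")
  clusters$ppm <- sweep(clusters$counts, 2L, 1e6 / tot, `*`)
  attr(clusters, "lib_sizes") <- lib_sizes[libs]
  clusters
}

#' Filter clusters on a ppm expression threshold
#'
#' Keeps a cluster when its expression is strictly above `min_ppm` in at
#' least one library. Libraries were constructed and sequenced
#' independently, so a cluster well supported in any one tissue is retained.
#'
#' @param clusters Cluster table with ppm computed (see [compute_ppm()]).
#' @param min_ppm Strict threshold in ppm (default 5).
#' @return The filtered cluster table.
#' @export
filter_clusters <- function(clusters, min_ppm = 5) {
  if (is.null(clusters$ppm)) stop("ppm not computed; call compute_ppm() first")
  best <- apply(clusters$ppm, 1L, max)
  out <- clusters[best > min_ppm, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "bin_size") <- attr(clusters, "bin_size")
  attr(out, "kind") <- attr(clusters, "kind")
  attr(out, "lib_sizes") <- attr(clusters, "lib_sizes")
  out
}

#' Poisson significance of tag concentration in a cluster
#'
#' Tests whether `k` tags in one `w`-bp bin are more concentrated than
#' expected if the gene's `N_gene` same-kind tags were scattered uniformly
#' along its mature mRNA of length `L`. Under that null the bin count is
#' Poisson with mean `lambda = N_gene * min(w, L) / L`, and the p-value is
#' the upper tail `P(X >= k)`.
#'
#' @param k Observed tag count in the cluster (vectorised).
#' @param N_gene Total same-kind tags of the host gene.
#' @param L Mature mRNA length in bp (sum of exon widths).
#' @param w Bin width in bp (default 500).
#' @return A `data.frame` with columns `k`, `N_gene`, `L`, `w`, `lambda`,
#'   `p_value`.
#' @examples
#' cluster_poisson_pvalue(k = 10, N_gene = 10, L = 1000)
#' @export
cluster_poisson_pvalue <- function(k, N_gene, L, w = 500) {
  if (any(L <= 0)) stop("L must be positive")
  if (any(w <= 0)) stop("w must be positive")
  if (any(k < 0) || any(N_gene < k)) stop("need 0 <= k <= N_gene")
  n <- max(length(k), length(N_gene), length(L), length(w))
  k <- rep_len(k, n); N_gene <- rep_len(N_gene, n)
  L <- rep_len(L, n); w <- rep_len(w, n)
  lambda <- N_gene * pmin(w, L) / L
  p <- stats::ppois(k - 1, lambda, lower.tail = FALSE)
  data.frame(k = k, N_gene = N_gene, L = L, w = w, lambda = lambda,
             p_value = p)
}

#' Write clusters as BED6 plus count/ppm columns
#'
#' @param clusters Cluster table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  score <- clusters$n_tags
  bed <- data.frame(clusters$chrom, clusters$start, clusters$end,
                    clusters$cluster_id, score, clusters$strand)
  if (!is.null(clusters$ppm)) {
    bed <- cbind(bed, round(clusters$ppm, 6))
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
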