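# GRanges from 0-based half-open intervals over an explicit seqlevel
# universe (so overlap queries between tables built from different
# chromosome sets stay silent).
.gr <- function(chrom, start0, end0, strand = NULL, levels = NULL) {
  GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = levels %||% unique(chrom)),
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand %||% "*"
  )
}

.cluster_granges <- function(clusters, levels = NULL) {
  .gr(clusters$chrom, clusters$start, clusters$end, clusters$strand, levels)
}

# Terminal-exon and flank windows of each gene, in transcript orientation.
.gene_regions <- function(genes, max_dist) {
  n <- nrow(genes)
  plus <- genes$strand == "+"
  first_s <- integer(n); first_e <- integer(n)
  last_s <- integer(n); last_e <- integer(n)
  for (i in seq_len(n)) {
    ex_s <- genes$exon_starts[[i]]; ex_e <- genes$exon_ends[[i]]
    k <- length(ex_s)
    if (plus[i]) {
      first_s[i] <- ex_s[1]; first_e[i] <- ex_e[1]
      last_s[i] <- ex_s[k]; last_e[i] <- ex_e[k]
    } else {
      first_s[i] <- ex_s[k]; first_e[i] <- ex_e[k]
      last_s[i] <- ex_s[1]; last_e[i] <- ex_e[1]
    }
  }
  list(
    upstream_s = ifelse(plus, pmax(0L, genes$tx_start - max_dist),
                        genes$tx_end),
    upstream_e = ifelse(plus, genes$tx_start, genes$tx_end + max_dist),
    downstream_s = ifelse(plus, genes$tx_end,
                          pmax(0L, genes$tx_start - max_dist)),
    downstream_e = ifelse(plus, genes$tx_end + max_dist, genes$tx_start),
    first_s = first_s, first_e = first_e,
    last_s = last_s, last_e = last_e
  )
}

.internal_exon_granges <- function(genes, levels = NULL) {
  idx <- integer(0); st <- integer(0); en <- integer(0)
  for (i in seq_len(nrow(genes))) {
    ex_s <- genes$exon_starts[[i]]; ex_e <- genes$exon_ends[[i]]
    k <- length(ex_s)
    if (k > 2L) {
      idx <- c(idx, rep.int(i, k - 2L))
      st <- c(st, ex_s[2:(k - 1L)])
      en <- c(en, ex_e[2:(k - 1L)])
    }
  }
  gr <- .gr(genes$chrom[idx], st, en, genes$strand[idx], levels)
  S4Vectors::mcols(gr)$gene <- idx
  gr
}

#' Associate TSCs/PACs with gene models
#'
#' A TSC is linked to a gene when its bin overlaps the window extending
#' `max_dist` bp upstream of the annotated 5'-end or lies in the first exon;
#' a PAC when its bin overlaps the window `max_dist` bp downstream of the
#' 3'-end or lies in the last exon. Clusters overlapping internal exons are
#' reported but flagged `excluded` and never linked: an end tag inside an
#' internal exon is more plausibly a truncation or internal-priming
#' artefact than a genuine transcript boundary. A cluster may link to
#' several genes.
#'
#' @param clusters Cluster table from [cluster_tags()] (kind TSC or PAC).
#' @param genes Gene-model table from [read_gene_models()].
#' @param max_dist Flank window in bp (default 50000).
#' @return A `data.frame` with columns `cluster_id`, `gene_id`, `kind`,
#'   `relation` (`upstream_50kb`, `first_exon`, `last_exon`,
#'   `downstream_50kb`, `internal`), `distance` (signed bp of `rep_pos` from
#'   the relevant transcript terminus, transcript-oriented: negative is
#'   upstream) and `excluded`.
#' @export
associate_clusters <- function(clusters, genes, max_dist = 50000) {
  kind <- attr(clusters, "kind") %||% clusters$kind[1]
  empty <- data.frame(cluster_id = character(0), gene_id = character(0),
                      kind = character(0), relation = character(0),
                      distance = integer(0), excluded = logical(0))
  if (nrow(clusters) == 0L || nrow(genes) == 0L) return(empty)
  lv <- union(clusters$chrom, genes$chrom)
  reg <- .gene_regions(genes, max_dist)
  cl_gr <- .cluster_granges(clusters, lv)
  tss <- gene_tss(genes); pas <- gene_pas(genes)
  if (kind == "TSC") {
    win_s <- reg$upstream_s; win_e <- reg$upstream_e
    ex_s <- reg$first_s; ex_e <- reg$first_e
    terminus <- tss
    win_rel <- "upstream_50kb"; ex_rel <- "first_exon"
  } else {
    win_s <- reg$downstream_s; win_e <- reg$downstream_e
    ex_s <- reg$last_s; ex_e <- reg$last_e
    terminus <- pas
    win_rel <- "downstream_50kb"; ex_rel <- "last_exon"
  }
  mk_gr <- function(s, e) .gr(genes$chrom, s, e, genes$strand, lv)
  hit_win <- GenomicRanges::findOverlaps(cl_gr, mk_gr(win_s, win_e))
  hit_ex <- GenomicRanges::findOverlaps(cl_gr, mk_gr(ex_s, ex_e))
  link <- unique(rbind(as.matrix(hit_win), as.matrix(hit_ex)))
  rows <- list()
  if (nrow(link) > 0L) {
    ci <- link[, 1]; gi <- link[, 2]
    rp <- clusters$rep_pos[ci]
    in_ex <- rp >= ex_s[gi] & rp < ex_e[gi]
    sign <- ifelse(genes$strand[gi] == "+", 1L, -1L)
    rows$linked <- data.frame(
      cluster_id = clusters$cluster_id[ci],
      gene_id = genes$gene_id[gi],
      kind = kind,
      relation = ifelse(in_ex, ex_rel, win_rel),
      distance = sign * (rp - terminus[gi]),
      excluded = FALSE,
      stringsAsFactors = FALSE
    )
  }
  int_gr <- .internal_exon_granges(genes, lv)
  if (length(int_gr) > 0L) {
    hit_int <- GenomicRanges::findOverlaps(cl_gr, int_gr)
    if (length(hit_int) > 0L) {
      ci <- S4Vectors::queryHits(hit_int)
      gi <- S4Vectors::mcols(int_gr)$gene[S4Vectors::subjectHits(hit_int)]
      d <- unique(data.frame(ci = ci, gi = gi))
      already <- if (is.null(rows$linked)) character(0) else
        paste(rows$linked$cluster_id, rows$linked$gene_id)
      keep <- !(paste(clusters$cluster_id[d$ci], genes$gene_id[d$gi]) %in%
                  already)
      d <- d[keep, , drop = FALSE]
      if (nrow(d) > 0L) {
        rows$internal <- data.frame(
          cluster_id = clusters$cluster_id[d$ci],
          gene_id = genes$gene_id[d$gi],
          kind = kind,
          relation = "internal",
          distance = NA_integer_,
          excluded = TRUE,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$cluster_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Primary gene of each linked cluster
#'
#' When a cluster links to several genes, the link whose `rep_pos` is
#' closest to the gene terminus wins (ties broken by gene id). Excluded
#' (internal-exon) links never map.
#'
#' @param links Link table from [associate_clusters()].
#' @return Named character vector, `cluster_id` to `gene_id`.
#' @export
cluster_gene_map <- function(links) {
  ok <- links[!links$excluded, , drop = FALSE]
  if (nrow(ok) == 0L) return(stats::setNames(character(0), character(0)))
  ok <- ok[order(ok$cluster_id, abs(ok$distance), ok$gene_id), , drop = FALSE]
  ok <- ok[!duplicated(ok$cluster_id), , drop = FALSE]
  stats::setNames(ok$gene_id, ok$cluster_id)
}

#' Classify tag positions relative to transcript models
#'
#' Assigns every tag end exactly one category among `first_exon`,
#' `last_exon`, `internal_exon`, `intron`, `upstream`, `downstream`,
#' `intergenic` (the first match in that precedence order across all
#' strand-matched gene models; flanks extend `max_dist` bp). Categories
#' partition the input, so the reported fractions sum to one.
#'
#' @param tags `data.frame` with `chrom`, `pos`, `strand`.
#' @param genes Gene-model table.
#' @param max_dist Flank in bp (default 50000).
#' @return A list with `category` (character vector, one per tag) and
#'   `fractions` (named numeric summing to 1).
#' @export
classify_tag_positions <- function(tags, genes, max_dist = 50000) {
  cats <- c("first_exon", "last_exon", "internal_exon", "intron",
            "upstream", "downstream", "intergenic")
  n <- nrow(tags)
  rank <- rep(7L, n)
  lv <- union(tags$chrom, genes$chrom)
  tag_gr <- .gr(tags$chrom, tags$pos, tags$pos + 1L, tags$strand, lv)
  reg <- .gene_regions(genes, max_dist)
  mk <- function(s, e) {
    keep <- e > s
    .gr(genes$chrom[keep], s[keep], e[keep], genes$strand[keep], lv)
  }
  mark <- function(gr, r) {
    if (length(gr) == 0L) return(invisible())
    hits <- S4Vectors::queryHits(GenomicRanges::findOverlaps(tag_gr, gr))
    rank[hits] <<- pmin(rank[hits], r)
    invisible()
  }
  mark(mk(reg$first_s, reg$first_e), 1L)
  mark(mk(reg$last_s, reg$last_e), 2L)
  mark(.internal_exon_granges(genes, lv), 3L)
  mark(mk(genes$tx_start, genes$tx_end), 4L)  # gene body; exons already won
  mark(mk(reg$upstream_s, reg$upstream_e), 5L)
  mark(mk(reg$downstream_s, reg$downstream_e), 6L)
  category <- cats[rank]
  fr <- table(factor(category, levels = cats)) / max(n, 1L)
  list(category = category, fractions = c(fr))
}

.scan_windows <- function(genome, clusters, window, extend) {
  lapply(seq_len(nrow(clusters)), function(i) {
    .window_seq(genome, clusters$chrom[i], clusters$rep_pos[i],
                clusters$strand[i], window[1], window[2] + extend)
  })
}

.motif_offsets <- function(ws, pattern, window) {
  m <- gregexpr(pattern, ws$seq)[[1]]
  if (m[1] == -1L) return(integer(0))
  rel <- window[1] + ws$clip5 + (as.integer(m) - 1L)
  sort(rel[rel >= window[1] & rel < window[2]])
}

#' Scan for the canonical poly(A)-addition signal near PACs
#'
#' Looks for perfect `AATAAA` hexamers starting on the sense strand within
#' `window` (transcript-relative to `rep_pos`; the default `[-40, 0)`
#' covers the canonical placement ~10-30 bp upstream of cleavage).
#'
#' @param genome A [Biostrings::DNAStringSet] named by chromosome.
#' @param pacs PAC cluster table.
#' @param window Integer pair, transcript-relative `[from, to)` (default
#'   `c(-40, 0)`).
#' @return `data.frame` with `cluster_id`, `polya_signal` (logical) and a
#'   list column `offsets` (hexamer start offsets, 5' to 3').
#' @export
scan_polya_signal <- function(genome, pacs, window = c(-40, 0)) {
  ws <- .scan_windows(genome, pacs, window, extend = 5L)
  offs <- lapply(ws, .motif_offsets, pattern = "AATAAA", window = window)
  out <- data.frame(cluster_id = pacs$cluster_id,
                    polya_signal = lengths(offs) > 0L,
                    stringsAsFactors = FALSE)
  out$offsets <- offs
  out
}

#' Flag genomic poly(A) stretches downstream of PACs (internal priming)
#'
#' A run of at least `min_run` consecutive genomic `A` on the sense strand
#' immediately downstream of the cleavage base can serve as a spurious
#' oligo-dT priming site; PACs flagged here are internal-priming risks.
#'
#' @param genome A [Biostrings::DNAStringSet] named by chromosome.
#' @param pacs PAC cluster table.
#' @param window Transcript-relative `[from, to)` window (default
#'   `c(1, 21)`, i.e. the 20 bases after the cleavage base).
#' @param min_run Minimum run length (default 6).
#' @return `data.frame` with `cluster_id` and `polya_stretch` (logical).
#' @export
scan_polya_stretch <- function(genome, pacs, window = c(1, 21), min_run = 6) {
  ws <- .scan_windows(genome, pacs, window, extend = 0L)
  pat <- sprintf("A{%d}", min_run)
  hit <- vapply(ws, function(w) grepl(pat, w$seq), FALSE)
  data.frame(cluster_id = pacs$cluster_id, polya_stretch = hit,
             stringsAsFactors = FALSE)
}

#' Scan for TATA boxes upstream of TSCs
#'
#' Matches the IUPAC consensus `TATAWAWR` (W = A/T, R = A/G) starting on the
#' sense strand within `window` upstream of the representative TSS.
#'
#' @param genome A [Biostrings::DNAStringSet] named by chromosome.
#' @param tscs TSC cluster table.
#' @param window Transcript-relative `[from, to)` window of allowed motif
#'   starts (default `c(-40, -20)`).
#' @return `data.frame` with `cluster_id` and `tata` (logical).
#' @export
scan_tata <- function(genome, tscs, window = c(-40, -20)) {
  ws <- .scan_windows(genome, tscs, window, extend = 7L)
  offs <- lapply(ws, .motif_offsets, pattern = "TATA[AT]A[AT][AG]",
                 window = window)
  data.frame(cluster_id = tscs$cluster_id, tata = lengths(offs) > 0L,
             stringsAsFactors = FALSE)
}

#' Flag TSCs overlapping CpG islands
#'
#' @param tscs TSC cluster table.
#' @param cpg_islands `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [read_bed()].
#' @return Logical vector: the cluster bin overlaps an island by >= 1 bp.
#' @export
annotate_cpg <- function(tscs, cpg_islands) {
  if (nrow(tscs) == 0L) return(logical(0))
  lv <- union(tscs$chrom, cpg_islands$chrom)
  cl <- .gr(tscs$chrom, tscs$start, tscs$end, levels = lv)
  isl <- .gr(cpg_islands$chrom, cpg_islands$start, cpg_islands$end,
             levels = lv)
  GenomicRanges::countOverlaps(cl, isl, ignore.strand = TRUE) > 0L
}

#' Mutual coverage of two cluster sets
#'
#' Reports the fraction of clusters in `set_a` overlapped (within `slop` bp)
#' by at least one cluster of `set_b`, and vice versa; the two directions
#' are asymmetric by construction.
#'
#' @param set_a,set_b Cluster tables (same assembly, same kind).
#' @param slop Maximum gap in bp still counted as overlap; 0 (the default)
#'   requires a genuine >= 1 bp bin overlap.
#' @return Named numeric `c(a_in_b =, b_in_a =)`.
#' @export
compare_cluster_sets <- function(set_a, set_b, slop = 0) {
  if (nrow(set_a) == 0L) stop("set_a is empty")
  if (nrow(set_b) == 0L) stop("set_b is empty")
  lv <- union(set_a$chrom, set_b$chrom)
  gr_a <- .cluster_granges(set_a, lv)
  gr_b <- .cluster_granges(set_b, lv)
  mg <- if (slop == 0) -1L else as.integer(slop)
  a_in_b <- GenomicRanges::countOverlaps(gr_a, gr_b, maxgap = mg) > 0L
  b_in_a <- GenomicRanges::countOverlaps(gr_b, gr_a, maxgap = mg) > 0L
  c(a_in_b = mean(a_in_b), b_in_a = mean(b_in_a))
}

#' Read a BED file into a 0-based interval table
#'
#' @param path BED3/BED6 file.
#' @return `data.frame` with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$name)) out$name <- mc$name
  if (!is.null(mc$score)) out$score <- mc$score
  s <- as.character(GenomicRanges::strand(gr))
  if (any(s != "*")) out$strand <- s
  out
}
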