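# Internal helpers shared across modules. Coordinates are 0-based half-open
# throughout; `pos` of an end tag is the single base representing the
# transcript end (for a PAS tag, the last transcribed base).

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom data.table data.table := .N .SD setkey as.data.table rbindlist setorder
NULL

.cluster_key <- function(chrom, strand, pos, bin_size) {
  paste(chrom, strand, pos %/% bin_size, sep = ":")
}

# Transcript-oriented window around an anchor base. Offsets are relative to
# `pos` in transcript direction: 0 is the anchor base itself, negative is
# upstream. Returns the sense-strand sequence of [from, to) as a character
# string, clipped to chromosome bounds (with how much was clipped at the 5'
# side, so callers can keep offsets honest).
.window_seq <- function(genome, chrom, pos, strand, from, to) {
  stopifnot(from < to)
  len <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (is.na(len)) stop("chromosome not in genome: ", chrom)
  if (strand == "+") {
    g1 <- pos + from
    g2 <- pos + to
  } else {
    g1 <- pos - to + 1L
    g2 <- pos - from + 1L
  }
  c1 <- max(g1, 0L)
  c2 <- min(g2, len)
  if (c1 >= c2) {
    return(list(seq = "", clip5 = 0L))
  }
  s <- Biostrings::subseq(genome[[chrom]], start = c1 + 1L, end = c2)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  clip5 <- if (strand == "+") c1 - g1 else g2 - c2
  list(seq = as.character(s), clip5 = as.integer(clip5))
}

# Cumulative exon structure of one gene (row of a gene-model table).
.exon_frame <- function(gene) {
  st <- gene$exon_starts[[1]]
  en <- gene$exon_ends[[1]]
  w <- en - st
  list(starts = st, ends = en, widths = w, cum = cumsum(c(0L, w)),
       len = sum(w))
}

# Map mRNA offsets (0-based from the 5' end of the mature transcript) to
# genomic coordinates for one gene. Vectorised over `offsets`.
.mrna_to_genomic <- function(gene, offsets) {
  ef <- .exon_frame(gene)
  if (any(offsets < 0L | offsets >= ef$len)) stop("mRNA offset out of range")
  if (gene$strand == "-") offsets <- ef$len - 1L - offsets
  idx <- findInterval(offsets, ef$cum[-length(ef$cum)])
  ef$starts[idx] + (offsets - ef$cum[idx])
}

# Map genomic positions to mRNA offsets for one gene; NA outside exons.
.genomic_to_mrna <- function(gene, gpos) {
  ef <- .exon_frame(gene)
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_along(ef$starts)) {
    hit <- gpos >= ef$starts[i] & gpos < ef$ends[i]
    out[hit] <- ef$cum[i] + (gpos[hit] - ef$starts[i])
  }
  if (gene$strand == "-") out <- ef$len - 1L - out
  out
}

# Absolute [start, end) block intervals of a 3' tag from its ENDPAIR
# encoding. Block start offsets are relative to the leftmost aligned base;
# on '+' the anchor `pos` is the rightmost aligned base (the transcript
# 3'-most base), on '-' it is the leftmost.
.tag_blocks_abs <- function(pos, strand, sizes, starts) {
  if (length(sizes) == 0L) {
    return(cbind(start = pos, end = pos + 1L))
  }
  span <- starts[length(starts)] + sizes[length(sizes)]
  left <- if (strand == "+") pos - span + 1L else pos
  cbind(start = left + starts, end = left + starts + sizes)
}

.parse_int_list <- function(x) {
  if (is.na(x) || x == "." || x == "") return(integer(0))
  as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
}

.format_int_list <- function(v) {
  if (length(v) == 0L) "." else paste(v, collapse = ",")
}

# Gap in bp between two 0-based half-open intervals; 0 when they overlap.
.interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2))
}
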