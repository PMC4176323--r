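#' Read a bedGraph coverage file
#'
#' @param path bedGraph file.
#' @return `data.frame` with `chrom`, `start`, `end` (0-based half-open)
#'   and `value`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             value = S4Vectors::mcols(gr)$score,
             stringsAsFactors = FALSE)
}

.coverage_rle <- function(cov, chroms, lens) {
  out <- lapply(chroms, function(ch) {
    d <- cov[cov$chrom == ch, , drop = FALSE]
    if (nrow(d) == 0L) {
      return(S4Vectors::Rle(0, lens[[ch]]))
    }
    ir <- IRanges::IRanges(start = d$start + 1L, end = d$end)
    IRanges::coverage(ir, weight = d$value, width = lens[[ch]])
  })
  names(out) <- chroms
  out
}

#' Fold-density track of ChIP signal over input
#'
#' Bins both coverages on a fixed `bin_size` grid and computes, per bin,
#' `fold = (ip_bin/ip_total + eps) / (input_bin/input_total + eps)`: the
#' immunoprecipitation density normalised by sequencing depth, divided by
#' the equally normalised input density, with a pseudocount so bins without
#' input coverage stay finite. The track stores the per-coordinate fold
#' (constant within a bin).
#'
#' @param ip_cov,input_cov Coverage tables from [read_bedgraph()] (columns
#'   `chrom`, `start`, `end`, `value`).
#' @param bin_size Bin width in bp (default 50).
#' @param pseudocount Density pseudocount `eps` (default 1e-9).
#' @return An object of class `fold_track`: list with `bin_size` and
#'   `values`, a per-chromosome [S4Vectors::Rle] of fold values.
#' @export
fold_density <- function(ip_cov, input_cov, bin_size = 50,
                         pseudocount = 1e-9) {
  ip_total <- sum(ip_cov$value * (ip_cov$end - ip_cov$start))
  in_total <- sum(input_cov$value * (input_cov$end - input_cov$start))
  if (ip_total <= 0 || in_total <= 0) stop("zero total coverage")
  chroms <- sort(unique(c(ip_cov$chrom, input_cov$chrom)))
  lens <- lapply(chroms, function(ch) {
    m <- max(c(0L, ip_cov$end[ip_cov$chrom == ch],
               input_cov$end[input_cov$chrom == ch]))
    as.integer(ceiling(m / bin_size) * bin_size)
  })
  names(lens) <- chroms
  ip_rle <- .coverage_rle(ip_cov, chroms, lens)
  in_rle <- .coverage_rle(input_cov, chroms, lens)
  values <- lapply(chroms, function(ch) {
    n_bins <- lens[[ch]] %/% bin_size
    if (n_bins == 0L) return(S4Vectors::Rle(numeric(0)))
    v <- IRanges::Views(ip_rle[[ch]],
                        start = seq_len(n_bins) * bin_size - bin_size + 1L,
                        width = bin_size)
    ip_bin <- IRanges::viewSums(v)
    v <- IRanges::Views(in_rle[[ch]],
                        start = seq_len(n_bins) * bin_size - bin_size + 1L,
                        width = bin_size)
    in_bin <- IRanges::viewSums(v)
    fold <- (ip_bin / ip_total + pseudocount) /
      (in_bin / in_total + pseudocount)
    S4Vectors::Rle(as.numeric(fold), rep.int(bin_size, n_bins))
  })
  names(values) <- chroms
  structure(list(bin_size = bin_size, values = values),
            class = "fold_track")
}

.track_values <- function(track, chrom, start, end) {
  rle <- track$values[[chrom]]
  if (is.null(rle)) stop("chromosome not in track: ", chrom)
  len <- length(rle)
  s <- max(start, 0L); e <- min(end, len)
  if (s >= e) stop("region has no defined bins")
  as.numeric(S4Vectors::window(rle, start = s + 1L, end = e))
}

#' Coordinate of maximal fold density within a region
#'
#' Returns the genomic coordinate attaining the largest fold density in the
#' region; ties resolve to the smallest coordinate.
#'
#' @param track A `fold_track` from [fold_density()].
#' @param region List or data.frame row with `chrom`, `start`, `end`.
#' @return A single genomic coordinate (0-based).
#' @export
center_on_max <- function(track, region) {
  v <- .track_values(track, region$chrom, region$start, region$end)
  max(region$start, 0L) + which.max(v) - 1L
}

#' Metaprofile of fold density over a set of regions
#'
#' In `scaled` mode every region is resampled onto `n_bins` equal-width
#' bins (bin `i` averages the fold values of coordinates
#' `[L*i/n, L*(i+1)/n)` of the region), so regions of different lengths are
#' comparable; regions shorter than `n_bins` bp are skipped. In `centered`
#' mode each region contributes the fold values of the fixed window
#' `[center - flank_bp, center + flank_bp)` around its midpoint. Minus
#' strand regions are flipped so the profile reads 5' to 3'. The profile is
#' the per-bin mean over regions.
#'
#' @param track A `fold_track`.
#' @param regions `data.frame` with `chrom`, `start`, `end` and optionally
#'   `strand`.
#' @param mode `"scaled"` or `"centered"`.
#' @param n_bins Number of bins in scaled mode (default 100).
#' @param flank_bp Flank in bp in centered mode (default 5000).
#' @return List with `mode`, `n_regions`, `n_skipped` and `profile`
#'   (numeric vector of per-bin means).
#' @export
metaprofile <- function(track, regions, mode = c("scaled", "centered"),
                        n_bins = 100, flank_bp = 5000) {
  mode <- match.arg(mode)
  if (nrow(regions) == 0L) stop("need >= 1 region")
  strand <- regions$strand %||% rep("+", nrow(regions))
  prof <- NULL
  n_used <- 0L; n_skipped <- 0L
  for (i in seq_len(nrow(regions))) {
    if (mode == "scaled") {
      L <- regions$end[i] - regions$start[i]
      if (L < n_bins) { n_skipped <- n_skipped + 1L; next }
      v <- .track_values(track, regions$chrom[i], regions$start[i],
                         regions$end[i])
      if (strand[i] == "-") v <- rev(v)
      edges <- floor(L * seq(0L, n_bins) / n_bins)
      row <- vapply(seq_len(n_bins), function(b) {
        mean(v[(edges[b] + 1L):edges[b + 1L]])
      }, 0)
    } else {
      ctr <- (regions$start[i] + regions$end[i]) %/% 2L
      rle <- track$values[[regions$chrom[i]]]
      if (is.null(rle) || ctr - flank_bp < 0L ||
          ctr + flank_bp > length(rle)) {
        n_skipped <- n_skipped + 1L; next
      }
      row <- .track_values(track, regions$chrom[i], ctr - flank_bp,
                           ctr + flank_bp)
      if (strand[i] == "-") row <- rev(row)
    }
    prof <- if (is.null(prof)) row else prof + row
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("all regions skipped")
  list(mode = mode, n_regions = n_used, n_skipped = n_skipped,
       profile = prof / n_used)
}

#' Peak frequency and density over region sets
#'
#' For each region set reports the fraction of regions containing at least
#' one peak and the per-region peak density (peaks per kb), for comparing
#' e.g. the regions separating preferred TSC-PAC units against other
#' intronic regions.
#'
#' @param peaks `data.frame` with `chrom`, `start`, `end` (e.g. from
#'   [read_bed()]).
#' @param separating_regions,control_regions Region tables (`chrom`,
#'   `start`, `end`); `control_regions` may be `NULL`.
#' @return List with one entry per supplied set: `frequency` (fraction of
#'   regions with >= 1 peak) and `density` (numeric vector, peaks per kb
#'   per region).
#' @export
peak_frequency_between_units <- function(peaks, separating_regions,
                                         control_regions = NULL) {
  lv <- unique(c(peaks$chrom, separating_regions$chrom,
                 control_regions$chrom))
  pk <- GenomicRanges::GRanges(factor(peaks$chrom, lv),
                               IRanges::IRanges(peaks$start + 1L,
                                                peaks$end))
  one <- function(rg) {
    gr <- GenomicRanges::GRanges(factor(rg$chrom, lv),
                                 IRanges::IRanges(rg$start + 1L, rg$end))
    n <- GenomicRanges::countOverlaps(gr, pk, ignore.strand = TRUE)
    list(frequency = mean(n > 0L),
         density = n / ((rg$end - rg$start) / 1000))
  }
  out <- list(separating = one(separating_regions))
  if (!is.null(control_regions)) out$control <- one(control_regions)
  out
}
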