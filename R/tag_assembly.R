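#' Genome-guided assembly of tags between a TSC and a PAC
#'
#' Labels every genomic coordinate between the two representative end
#' positions: `transcript` when covered by at least one aligned tag block,
#' `intron` when spanned by the gap of at least one split tag, `unknown`
#' otherwise. A coordinate both covered and spanned is labelled
#' `transcript` (direct coverage is the stronger evidence). The integrity
#' of the model is the fraction of coordinates labelled transcript or
#' intron.
#'
#' @param tags `data.frame` of tags on the region's chromosome and strand
#'   with columns `pos`, `strand` and (for split tags) `blocks_sizes`,
#'   `blocks_starts` as comma strings (ENDPAIR encoding; `.` or missing
#'   columns mean single-base tags).
#' @param region Integer pair `c(start, end)` (0-based half-open), TSC
#'   `rep_pos` to PAC `rep_pos` oriented genomically.
#' @return An object of class `assembly_model`: list with `region`,
#'   `labels` (character vector, one per coordinate), `exons` (matrix of
#'   `[start, end)` transcript intervals), `introns`, `integrity` and
#'   `assembled_length`.
#' @examples
#' tags <- data.frame(pos = 499L, strand = "+",
#'                    blocks_sizes = "200,200", blocks_starts = "0,300")
#' assemble_region(tags, c(0L, 500L))
#' @export
assemble_region <- function(tags, region) {
  start <- as.integer(region[1]); end <- as.integer(region[2])
  if (end <= start) stop("empty assembly region")
  len <- end - start
  covered <- logical(len)
  gapped <- logical(len)
  n <- nrow(tags)
  sizes_col <- tags$blocks_sizes %||% rep(".", n)
  starts_col <- tags$blocks_starts %||% rep(".", n)
  clip <- function(s, e) c(max(s, start), min(e, end))
  for (i in seq_len(n)) {
    blk <- .tag_blocks_abs(as.integer(tags$pos[i]), tags$strand[i],
                           .parse_int_list(sizes_col[i]),
                           .parse_int_list(starts_col[i]))
    for (b in seq_len(nrow(blk))) {
      ce <- clip(blk[b, 1], blk[b, 2])
      if (ce[1] < ce[2]) {
        covered[(ce[1] - start + 1L):(ce[2] - start)] <- TRUE
      }
    }
    if (nrow(blk) > 1L) {
      for (b in seq_len(nrow(blk) - 1L)) {
        ce <- clip(blk[b, 2], blk[b + 1L, 1])
        if (ce[1] < ce[2]) {
          gapped[(ce[1] - start + 1L):(ce[2] - start)] <- TRUE
        }
      }
    }
  }
  labels <- ifelse(covered, "transcript",
                   ifelse(gapped, "intron", "unknown"))
  runs_of <- function(mask) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts_r <- ends - r$lengths
    cbind(start = start + starts_r[r$values],
          end = start + ends[r$values])
  }
  structure(list(
    region = c(start, end),
    labels = labels,
    exons = runs_of(labels == "transcript"),
    introns = runs_of(labels == "intron"),
    integrity = mean(labels != "unknown"),
    assembled_length = sum(labels == "transcript")
  ), class = "assembly_model")
}

#' Summarise assembled transcript models
#'
#' @param models List of `assembly_model` objects.
#' @param coverage_cut Strict integrity threshold for counting a model as
#'   successfully assembled (default 0.95).
#' @return List with `n_models`, `n_assembled` (integrity strictly above
#'   the cut), `integrity` and `assembled_length` vectors.
#' @export
assembly_report <- function(models, coverage_cut = 0.95) {
  integrity <- vapply(models, `[[`, 0, "integrity")
  lens <- vapply(models, `[[`, 0L, "assembled_length")
  list(n_models = length(models),
       n_assembled = sum(integrity > coverage_cut),
       integrity = integrity,
       assembled_length = lens)
}

#' Write assembly models as BED12
#'
#' One record per model; blocks are the transcript-labelled exons. Models
#' with no transcript-labelled coordinate are skipped.
#'
#' @param models List of `assembly_model` objects.
#' @param chrom,strand,name Per-model chromosome, strand and record name.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_assembly_bed <- function(models, chrom, strand, name, path) {
  lines <- character(0)
  for (i in seq_along(models)) {
    m <- models[[i]]
    ex <- m$exons
    if (nrow(ex) == 0L) next
    s <- ex[1, 1]; e <- ex[nrow(ex), 2]
    lines <- c(lines, paste(
      chrom[i], s, e, name[i], round(1000 * m$integrity), strand[i],
      s, e, 0L, nrow(ex),
      paste(ex[, 2] - ex[, 1], collapse = ","),
      paste(ex[, 1] - s, collapse = ","),
      sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' TSS-to-3'-tag distances in mRNA coordinates, per size fraction
#'
#' For TSS/Random libraries the distance between the 5' tag and the random
#' 3' tag, measured along the mature mRNA (introns excised via the gene
#' model), reflects the insert length of the size-fractionated cDNA.
#' Pairs whose two ends do not both fall in exons of one strand-matched
#' gene model are skipped and counted.
#'
#' @param pairs Pair table (RANDOM 3' ends are used; PAS pairs are
#'   accepted too, measuring full transcript lengths).
#' @param genes Gene-model table.
#' @param stats Library stats with `fraction_label` (see
#'   [read_tag_pairs()]).
#' @return List with `distances` (data.frame `library_id`,
#'   `fraction_label`, `distance`) and `n_skipped`.
#' @export
size_fraction_distance_check <- function(pairs, genes, stats) {
  lab <- stats::setNames(stats$fraction_label, stats$library_id)
  res_lib <- character(0); res_d <- integer(0)
  skipped <- 0L
  lv <- union(pairs$chrom5, genes$chrom)
  gene_gr <- GenomicRanges::GRanges(
    factor(genes$chrom, lv),
    IRanges::IRanges(genes$tx_start + 1L, genes$tx_end),
    strand = genes$strand)
  p_gr <- GenomicRanges::GRanges(
    factor(pairs$chrom5, lv),
    IRanges::IRanges(pairs$pos5 + 1L, width = 1L),
    strand = pairs$strand5)
  hits <- GenomicRanges::findOverlaps(p_gr, gene_gr)
  hit_list <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  for (i in seq_len(nrow(pairs))) {
    gis <- hit_list[[as.character(i)]]
    d <- NA_integer_
    if (!is.null(gis)) {
      for (gi in gis) {
        if (pairs$chrom3[i] != genes$chrom[gi]) next
        g <- genes[gi, ]
        m5 <- .genomic_to_mrna(g, pairs$pos5[i])
        m3 <- .genomic_to_mrna(g, pairs$pos3[i])
        if (!is.na(m5) && !is.na(m3)) {
          d <- abs(m3 - m5)
          break
        }
      }
    }
    if (is.na(d)) {
      skipped <- skipped + 1L
    } else {
      res_lib <- c(res_lib, pairs$library_id[i])
      res_d <- c(res_d, d)
    }
  }
  data_out <- data.frame(library_id = res_lib,
                         fraction_label = unname(lab[res_lib]),
                         distance = res_d, stringsAsFactors = FALSE)
  list(distances = data_out, n_skipped = skipped)
}
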