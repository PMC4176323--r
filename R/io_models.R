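#' Read gene models from refFlat or BED12
#'
#' Parses transcript models into the canonical gene-model table used by the
#' rest of the pipeline. Coordinates are converted to 0-based half-open
#' intervals (refFlat and BED already use this convention for starts/ends).
#' The coding class is inferred from the accession prefix of the record name
#' (`NM_` for protein-coding, `NR_` for putative non-coding transcripts).
#'
#' @param path Path to a refFlat (11-column, no header) or BED12 file.
#' @param format One of `"auto"`, `"refflat"`, `"bed12"`. `"auto"` picks
#'   BED12 for `.bed` extensions and refFlat otherwise.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`, `coding_class` and list columns `exon_starts`,
#'   `exon_ends` (sorted, non-overlapping, 0-based half-open).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t900\tNM_demo\t0\t+\t100\t900\t0\t2\t100,200\t0,600",
#'            bed)
#' read_gene_models(bed)
#' @export
read_gene_models <- function(path, format = c("auto", "refflat", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
      "bed12" else "refflat"
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) stop("no records in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_need <- if (format == "refflat") 11L else 12L
  bad <- which(lengths(fields) < ncol_need)
  if (length(bad) > 0L) {
    stop(sprintf("malformed %s line %d in %s: expected %d columns, got %d",
                 format, bad[1], path, ncol_need, length(fields[[bad[1]]])))
  }
  recs <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (format == "refflat") {
      gene_id <- f[2]
      chrom <- f[3]; strand <- f[4]
      tx_start <- as.integer(f[5]); tx_end <- as.integer(f[6])
      n_ex <- as.integer(f[9])
      ex_s <- .parse_int_list(sub(",$", "", f[10]))
      ex_e <- .parse_int_list(sub(",$", "", f[11]))
    } else {
      chrom <- f[1]
      tx_start <- as.integer(f[2]); tx_end <- as.integer(f[3])
      gene_id <- f[4]; strand <- f[6]
      n_ex <- as.integer(f[10])
      sizes <- .parse_int_list(sub(",$", "", f[11]))
      offs <- .parse_int_list(sub(",$", "", f[12]))
      ex_s <- tx_start + offs
      ex_e <- ex_s + sizes
    }
    if (is.na(tx_start) || is.na(tx_end) || !(strand %in% c("+", "-"))) {
      stop(sprintf("malformed %s line %d in %s", format, i, path))
    }
    if (length(ex_s) != n_ex || length(ex_e) != n_ex) {
      stop(sprintf("exon count mismatch for record '%s' (line %d)",
                   gene_id, i))
    }
    .validate_gene(gene_id, tx_start, tx_end, ex_s, ex_e, line = i)
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         tx_start = tx_start, tx_end = tx_end,
         coding_class = if (startsWith(gene_id, "NR_")) "NR" else "NM",
         exon_starts = list(ex_s), exon_ends = list(ex_e))
  })
  out <- data.frame(
    gene_id = vapply(recs, `[[`, "", "gene_id"),
    chrom = vapply(recs, `[[`, "", "chrom"),
    strand = vapply(recs, `[[`, "", "strand"),
    tx_start = vapply(recs, `[[`, 0L, "tx_start"),
    tx_end = vapply(recs, `[[`, 0L, "tx_end"),
    coding_class = vapply(recs, `[[`, "", "coding_class"),
    stringsAsFactors = FALSE
  )
  out$exon_starts <- lapply(recs, function(r) r$exon_starts[[1]])
  out$exon_ends <- lapply(recs, function(r) r$exon_ends[[1]])
  out
}

.validate_gene <- function(gene_id, tx_start, tx_end, ex_s, ex_e, line = NA) {
  where <- if (is.na(line)) gene_id else sprintf("%s (line %d)", gene_id, line)
  if (tx_start >= tx_end) stop("record ", where, ": tx_start >= tx_end")
  if (length(ex_s) == 0L) stop("record ", where, ": no exons")
  if (is.unsorted(ex_s, strictly = TRUE) ||
      any(ex_e <= ex_s) ||
      any(ex_s[-1] < ex_e[-length(ex_e)])) {
    stop("record ", where, ": exons must be sorted and non-overlapping")
  }
  if (ex_s[1] < tx_start || ex_e[length(ex_e)] > tx_end) {
    stop("record ", where, ": exons outside [tx_start, tx_end)")
  }
  invisible(TRUE)
}

#' Write gene models as BED12
#'
#' @param genes Gene-model table from [read_gene_models()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex_s <- g$exon_starts[[1]]
    ex_e <- g$exon_ends[[1]]
    paste(g$chrom, g$tx_start, g$tx_end, g$gene_id, 0L, g$strand,
          g$tx_start, g$tx_end, 0L, length(ex_s),
          paste(ex_e - ex_s, collapse = ","),
          paste(ex_s - g$tx_start, collapse = ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Mature mRNA length of each gene model
#'
#' Sum of exon widths in bp; the length scale on which tag concentration is
#' tested (tags derive from the mRNA, not the genomic span).
#'
#' @param genes Gene-model table.
#' @return Integer vector.
#' @export
mrna_length <- function(genes) {
  vapply(seq_len(nrow(genes)), function(i) {
    as.integer(sum(genes$exon_ends[[i]] - genes$exon_starts[[i]]))
  }, 0L)
}

#' Annotated end positions of gene models
#'
#' `gene_tss()` returns the first transcribed base, `gene_pas()` the last
#' transcribed base (both 0-based single coordinates, strand-aware).
#'
#' @param genes Gene-model table.
#' @return Integer vector of positions.
#' @export
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1L)
}

#' @rdname gene_tss
#' @export
gene_pas <- function(genes) {
  ifelse(genes$strand == "+", genes$tx_end - 1L, genes$tx_start)
}

.ENDPAIR_COLS <- c("library_id", "chrom5", "pos5", "strand5", "mapq5",
                   "chrom3", "pos3", "strand3", "mapq3", "end3_kind",
                   "blocks3_sizes", "blocks3_starts")

#' Read a mate-pair tag table (ENDPAIR v1)
#'
#' The ENDPAIR v1 dialect is a tab-separated table with header columns
#' `library_id, chrom5, pos5, strand5, mapq5, chrom3, pos3, strand3, mapq3,
#' end3_kind, blocks3_sizes, blocks3_starts`. Each row is one aligned
#' mate-pair: the 5' tag is a TSS tag; the 3' tag is a PAS or RANDOM tag.
#' `pos` is the single base representing the transcript end. Block columns
#' are comma lists (`.` when absent) encoding split alignments of RANDOM
#' tags, offsets relative to the leftmost aligned base.
#'
#' Rows failing the load-time QC (`mapq` below `min_mapq` on either end) are
#' dropped; per-library totals count the retained rows and are the ppm
#' denominators downstream.
#'
#' @param path Path to the TSV.
#' @param min_mapq QC threshold applied to both ends at load (default 10).
#' @param fraction_labels Optional named character vector mapping
#'   `library_id` to a size-fraction label (`dT`, `dR0.5`, `dR1.0`,
#'   `dR2.0`). Unlisted libraries are labelled `dT` if their 3' tags are PAS
#'   tags and `dR` otherwise.
#' @return A list with `pairs` (the table plus a `pair_id` column) and
#'   `stats` (`library_id`, `total_pairs`, `fraction_label`).
#' @export
read_tag_pairs <- function(path, min_mapq = 10, fraction_labels = NULL) {
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  miss <- setdiff(.ENDPAIR_COLS, hdr)
  if (length(miss) > 0L) {
    stop("missing ENDPAIR columns: ", paste(miss, collapse = ", "))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(library_id = "character",
                                         chrom5 = "character",
                                         strand5 = "character",
                                         chrom3 = "character",
                                         strand3 = "character",
                                         end3_kind = "character",
                                         blocks3_sizes = "character",
                                         blocks3_starts = "character"),
                          stringsAsFactors = FALSE)
  miss <- setdiff(.ENDPAIR_COLS, names(df))
  if (length(miss) > 0L) {
    stop("missing ENDPAIR columns: ", paste(miss, collapse = ", "))
  }
  df <- df[, .ENDPAIR_COLS]
  if (any(!df$end3_kind %in% c("PAS", "RANDOM"))) {
    stop("unknown end3_kind token: ",
         df$end3_kind[which(!df$end3_kind %in% c("PAS", "RANDOM"))[1]])
  }
  if (any(df$pos5 < 0L) || any(df$pos3 < 0L)) {
    stop("negative tag coordinates")
  }
  keep <- df$mapq5 >= min_mapq & df$mapq3 >= min_mapq
  df <- df[keep, , drop = FALSE]
  df$pair_id <- seq_len(nrow(df))
  rownames(df) <- NULL
  tot <- table(df$library_id)
  libs <- names(tot)
  lab <- vapply(libs, function(l) {
    if (!is.null(fraction_labels) && l %in% names(fraction_labels)) {
      return(unname(fraction_labels[l]))
    }
    kinds <- df$end3_kind[df$library_id == l]
    if (all(kinds == "PAS")) "dT" else "dR"
  }, "")
  stats <- data.frame(library_id = libs, total_pairs = as.integer(tot),
                      fraction_label = lab, stringsAsFactors = FALSE,
                      row.names = NULL)
  list(pairs = df, stats = stats)
}

#' Write a mate-pair tag table (ENDPAIR v1)
#'
#' @param pairs Pair table with the ENDPAIR v1 columns (a `pair_id` column,
#'   if present, is not written).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tag_pairs <- function(pairs, path) {
  utils::write.table(pairs[, .ENDPAIR_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify a raw read by its adaptor junction signature
#'
#' The cap-replacing adaptor ends in `CTGCTGCC` immediately before the first
#' transcribed base, so reads beginning with that signature carry a TSS tag.
#' The random-primed adaptor ends in `CTGCTGGG` and marks an internal
#' 3'-end. A leading homopolymer run of A (or T on the reverse read) of at
#' least `polya_min_run` bases marks an oligo-dT-primed PAS tag. The offset
#' is the 0-based position of the first base after the signature.
#'
#' @param read_seq Character vector of read sequences over `A,C,G,T,N`.
#' @param polya_min_run Minimum leading poly(A)/(T) run to call a PAS read
#'   (default 10, the oligo-dT primer length minus sequencing errors).
#' @return A `data.frame` with columns `kind` (`TSS`, `RANDOM3P`, `PAS`,
#'   `none`) and `offset` (NA for `none`).
#' @examples
#' detect_junction_signature(c("CTGCTGCCATGGTT", "CTGCTGGGATGGTT", "ATGGTT"))
#' @export
detect_junction_signature <- function(read_seq, polya_min_run = 10) {
  kind <- rep("none", length(read_seq))
  offset <- rep(NA_integer_, length(read_seq))
  is_tss <- startsWith(read_seq, "CTGCTGCC")
  is_rnd <- !is_tss & startsWith(read_seq, "CTGCTGGG")
  kind[is_tss] <- "TSS"; offset[is_tss] <- 8L
  kind[is_rnd] <- "RANDOM3P"; offset[is_rnd] <- 8L
  rest <- which(!is_tss & !is_rnd)
  if (length(rest) > 0L) {
    run <- regexpr(sprintf("^(A{%d,}|T{%d,})", polya_min_run, polya_min_run),
                   read_seq[rest])
    hit <- run > 0L
    kind[rest[hit]] <- "PAS"
    offset[rest[hit]] <- attr(run, "match.length")[hit]
  }
  data.frame(kind = kind, offset = offset, stringsAsFactors = FALSE)
}
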