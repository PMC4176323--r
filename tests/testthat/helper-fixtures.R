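# Programmatic fixtures; nothing is stored on disk.

# Hand-specified two-gene model set: one plus-strand, one minus-strand.
tiny_genes <- function() {
  g <- data.frame(
    gene_id = c("NM_T001", "NR_T002"),
    chrom = c("chrT", "chrT"),
    strand = c("+", "-"),
    tx_start = c(10000L, 200000L),
    tx_end = c(16000L, 208000L),
    coding_class = c("NM", "NR"),
    stringsAsFactors = FALSE
  )
  g$exon_starts <- list(c(10000L, 12000L, 14000L),
                        c(200000L, 203000L, 207000L))
  g$exon_ends <- list(c(10500L, 12800L, 16000L),
                      c(201000L, 204000L, 208000L))
  g
}

# Random valid gene models for round-trip and property tests.
rand_genes <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    k <- sample(1:6, 1)
    ex_w <- sample(50:400, k, replace = TRUE)
    in_w <- if (k > 1) sample(100:5000, k - 1, replace = TRUE) else integer(0)
    s0 <- sample(0:5e6, 1)
    st <- s0 + cumsum(c(0L, ex_w[-k] + in_w))
    cls <- sample(c("NM", "NR"), 1)
    list(gene_id = sprintf("%s_R%04d", cls, i),
         chrom = sample(c("chrA", "chrB"), 1),
         strand = sample(c("+", "-"), 1),
         tx_start = st[1], tx_end = st[k] + ex_w[k],
         coding_class = cls,
         ex_s = as.integer(st), ex_e = as.integer(st + ex_w))
  })
  g <- data.frame(
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = vapply(rows, `[[`, "", "strand"),
    tx_start = vapply(rows, function(r) as.integer(r$tx_start), 0L),
    tx_end = vapply(rows, function(r) as.integer(r$tx_end), 0L),
    coding_class = vapply(rows, `[[`, "", "coding_class"),
    stringsAsFactors = FALSE
  )
  g$exon_starts <- lapply(rows, `[[`, "ex_s")
  g$exon_ends <- lapply(rows, `[[`, "ex_e")
  g
}

rand_genome <- function(lens, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Biostrings::DNAStringSet(vapply(lens, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, ""))
}

# Build a cluster table directly from tag positions.
clusters_from_positions <- function(chrom, pos, strand, kind = "TSC",
                                    library_id = "libA", bin_size = 500) {
  cluster_tags(data.frame(chrom = chrom, pos = as.integer(pos),
                          strand = strand, library_id = library_id,
                          stringsAsFactors = FALSE),
               kind = kind, bin_size = bin_size)
}

# Minimal ENDPAIR pair rows from parallel vectors.
make_pairs <- function(chrom5, pos5, strand5, chrom3, pos3, strand3,
                       library_id = "libA", mapq = 60L,
                       end3_kind = "PAS") {
  n <- max(lengths(list(pos5, pos3)))
  data.frame(library_id = rep_len(library_id, n),
             chrom5 = rep_len(chrom5, n), pos5 = as.integer(pos5),
             strand5 = rep_len(strand5, n), mapq5 = rep_len(mapq, n),
             chrom3 = rep_len(chrom3, n), pos3 = as.integer(pos3),
             strand3 = rep_len(strand3, n), mapq3 = rep_len(mapq, n),
             end3_kind = rep_len(end3_kind, n),
             blocks3_sizes = ".", blocks3_starts = ".",
             pair_id = seq_len(n),
             stringsAsFactors = FALSE)
}
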