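test_that("TSC-gene association honours the 50-kb window and exclusions", {
  g <- tiny_genes()  # NM_T001: + strand, 5' end at 10000
  # bin overlapping the far edge of the upstream window
  far <- clusters_from_positions("chrT", 101L, "+", bin_size = 500)
  # (bin [0,500) starts 9500-10000 bp upstream of the 5' end)
  lk <- associate_clusters(far, g, max_dist = 50000)
  expect_equal(lk$gene_id, "NM_T001")
  expect_equal(lk$relation, "upstream_50kb")
  expect_equal(lk$distance, 101L - 10000L)
  # inside the first exon
  fe <- associate_clusters(clusters_from_positions("chrT", 10200L, "+"), g)
  expect_equal(fe$relation, "first_exon")
  expect_equal(fe$distance, 200L)
  # internal exon: reported but excluded
  int <- associate_clusters(clusters_from_positions("chrT", 12100L, "+"), g)
  expect_true(all(int$excluded))
  expect_equal(int$relation, "internal")
  # beyond the window: no link at all
  out <- associate_clusters(
    clusters_from_positions("chrT", 10000L - 60000L + 70000L * 0L, "+"), g)
  expect_equal(nrow(associate_clusters(
    clusters_from_positions("chrT2", 100L, "+"), g)), 0L)
})

test_that("association is strand-aware and works for PACs on minus genes", {
  g <- tiny_genes()  # NR_T002: - strand, 3' end (PAS) at 200000
  pac <- clusters_from_positions("chrT", 199000L, "-", kind = "PAC")
  lk <- associate_clusters(pac, g)
  expect_equal(lk$gene_id, "NR_T002")
  expect_equal(lk$relation, "downstream_50kb")
  expect_equal(lk$distance, 1000L)  # transcript-oriented downstream
  # last exon of the minus gene is its genomically first exon
  le <- associate_clusters(
    clusters_from_positions("chrT", 200500L, "-", kind = "PAC"), g)
  expect_equal(le$relation, "last_exon")
  # a plus-strand cluster at the same position does not link
  expect_equal(nrow(associate_clusters(
    clusters_from_positions("chrT", 199000L, "+", kind = "PAC"), g)), 0L)
})

test_that("association is invariant under whole-assembly translation", {
  g <- tiny_genes()
  cl <- clusters_from_positions("chrT", c(9000L, 10200L, 12100L), "+")
  lk1 <- associate_clusters(cl, g)
  shift <- 13500L
  g2 <- g
  g2$tx_start <- g$tx_start + shift; g2$tx_end <- g$tx_end + shift
  g2$exon_starts <- lapply(g$exon_starts, `+`, shift)
  g2$exon_ends <- lapply(g$exon_ends, `+`, shift)
  cl2 <- clusters_from_positions("chrT", c(9000L, 10200L, 12100L) + shift,
                                 "+")
  lk2 <- associate_clusters(cl2, g2)
  expect_equal(lk2$relation, lk1$relation)
  expect_equal(lk2$distance, lk1$distance)
  expect_equal(lk2$excluded, lk1$excluded)
})

test_that("tag position categories partition and match the lookup oracle", {
  g <- tiny_genes()
  expect_equal(classify_tag_positions(
    data.frame(chrom = "chrT", pos = 10000L, strand = "+"), g)$category,
    "first_exon")
  set.seed(21)
  n <- 1000
  tags <- data.frame(chrom = "chrT",
                     pos = sample(0:300000, n, TRUE),
                     strand = sample(c("+", "-"), n, TRUE))
  res <- classify_tag_positions(tags, g)
  expect_equal(sum(res$fractions), 1.0, tolerance = 1e-12)
  oracle <- vapply(seq_len(n), function(i) {
    classify_oracle(tags$chrom[i], tags$pos[i], tags$strand[i], g)
  }, "")
  expect_identical(res$category, oracle)
})

test_that("cluster-to-gene primary mapping prefers the nearest link", {
  links <- data.frame(
    cluster_id = c("c1", "c1", "c2"),
    gene_id = c("gA", "gB", "gC"),
    kind = "TSC",
    relation = c("upstream_50kb", "first_exon", "internal"),
    distance = c(-4000L, 10L, NA),
    excluded = c(FALSE, FALSE, TRUE)
  )
  m <- cluster_gene_map(links)
  expect_equal(unname(m["c1"]), "gB")
  expect_false("c2" %in% names(m))
})

test_that("poly(A)-signal scan finds AATAAA in the upstream window", {
  seqs <- rand_genome(c(chrZ = 2000L), seed = 31)
  s <- strsplit(as.character(seqs[["chrZ"]]), "")[[1]]
  s[980:1000] <- "C"  # clean slate around the window
  s[(1000 - 21 + 1):(1000 - 21 + 6)] <- c("A", "A", "T", "A", "A", "A")
  genome <- Biostrings::DNAStringSet(setNames(paste(s, collapse = ""),
                                              "chrZ"))
  pac <- clusters_from_positions("chrZ", 1000L, "+", kind = "PAC")
  hit <- scan_polya_signal(genome, pac)
  expect_true(hit$polya_signal)
  expect_true(-21L %in% hit$offsets[[1]])
  # truncated pentamer does not count
  s[(1000 - 21 + 6)] <- "C"
  s[950:979] <- "C"
  genome2 <- Biostrings::DNAStringSet(setNames(paste(s, collapse = ""),
                                               "chrZ"))
  expect_false(scan_polya_signal(genome2, pac)$polya_signal)
})

test_that("sequence scans agree with a reverse-complement oracle", {
  genome <- rand_genome(c(chrZ = 50000L), seed = 33)
  set.seed(34)
  pos <- sample(2000:48000, 300)
  strand <- sample(c("+", "-"), 300, TRUE)
  cl <- data.frame(cluster_id = sprintf("c%03d", seq_along(pos)),
                   kind = "PAC", chrom = "chrZ", strand = strand,
                   start = (pos %/% 500) * 500L,
                   end = (pos %/% 500) * 500L + 500L,
                   rep_pos = pos, stringsAsFactors = FALSE)
  got_sig <- scan_polya_signal(genome, cl)$polya_signal
  got_str <- scan_polya_stretch(genome, cl)$polya_stretch
  got_tata <- scan_tata(genome, cl)$tata
  for (i in seq_along(pos)) {
    w1 <- window_seq_oracle(genome, "chrZ", pos[i], strand[i], -40L, 5L)
    hits <- gregexpr("AATAAA", w1)[[1]]
    expect_equal(got_sig[i],
                 any(hits > 0 & hits - 1 - 40 < 0), info = i)
    w2 <- window_seq_oracle(genome, "chrZ", pos[i], strand[i], 1L, 21L)
    expect_equal(got_str[i], grepl("AAAAAA", w2), info = i)
    w3 <- window_seq_oracle(genome, "chrZ", pos[i], strand[i], -40L, -13L)
    th <- gregexpr("TATA[AT]A[AT][AG]", w3)[[1]]
    expect_equal(got_tata[i], any(th > 0 & th - 1 - 40 < -20), info = i)
  }
})

test_that("CpG-island annotation matches a pairwise overlap oracle", {
  cl <- clusters_from_positions("chr1", c(1200L, 5000L), "+")
  isl <- data.frame(chrom = "chr1", start = c(1400L, 9000L),
                    end = c(2000L, 9500L))
  expect_equal(annotate_cpg(cl, isl), c(TRUE, FALSE))
  set.seed(41)
  cl2 <- clusters_from_positions("chr1", sample(0:1e5, 200), "+")
  isl2 <- data.frame(chrom = "chr1", start = (s <- sample(0:1e5, 100)),
                     end = s + sample(50:2000, 100, TRUE))
  got <- annotate_cpg(cl2, isl2)
  oracle <- vapply(seq_len(nrow(cl2)), function(i) {
    any(cl2$start[i] < isl2$end & isl2$start < cl2$end[i])
  }, FALSE)
  expect_identical(got, oracle)
})

test_that("cluster-set comparison reports mutual coverage fractions", {
  a <- clusters_from_positions("chr1", c(100L, 5000L, 9000L), "+")
  expect_equal(unname(compare_cluster_sets(a, a)), c(1, 1))
  b <- clusters_from_positions("chr1", c(20000L, 30000L), "+")
  expect_equal(unname(compare_cluster_sets(a, b)), c(0, 0))
  expect_error(compare_cluster_sets(a[0, ], b), "empty")
  set.seed(43)
  r1 <- clusters_from_positions("chr1", sample(0:2e5, 150), "+")
  r2 <- clusters_from_positions("chr1", sample(0:2e5, 150), "+")
  got <- compare_cluster_sets(r1, r2)
  ov <- function(x, y) {
    vapply(seq_len(nrow(x)), function(i) {
      any(x$start[i] < y$end & y$start < x$end[i] &
            x$strand[i] == y$strand)
    }, FALSE)
  }
  expect_equal(unname(got), c(mean(ov(r1, r2)), mean(ov(r2, r1))))
})
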