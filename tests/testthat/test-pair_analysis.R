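# A reusable two-TSC / two-PAC gene with strongly coupled diagonal cells.
coupled_gene_fixture <- function(nAX = 90, nBY = 90, nAY = 10, nBX = 10) {
  tsc_pos <- c(A = 100L, B = 900L)
  pac_pos <- c(X = 20100L, Y = 20900L)
  n <- c(nAX, nAY, nBX, nBY)
  p5 <- rep(tsc_pos[c("A", "A", "B", "B")], n)
  p3 <- rep(pac_pos[c("X", "Y", "X", "Y")], n)
  pairs <- make_pairs("chrP", p5, "+", "chrP", p3, "+")
  tscs <- clusters_from_positions("chrP", p5, "+", kind = "TSC")
  pacs <- clusters_from_positions("chrP", p3, "+", kind = "PAC")
  pairs <- assign_pairs_to_clusters(pairs, tscs, pacs)
  gene <- data.frame(gene_id = "NM_P1", chrom = "chrP", strand = "+",
                     tx_start = 100L, tx_end = 20901L,
                     coding_class = "NM", stringsAsFactors = FALSE)
  gene$exon_starts <- list(c(100L, 20000L))
  gene$exon_ends <- list(c(1000L, 20901L))
  list(pairs = pairs,
       tsc_links = associate_clusters(tscs, gene),
       pac_links = associate_clusters(pacs, gene),
       tscs = tscs, pacs = pacs)
}

test_that("pair matrices tabulate counts with consistent marginals", {
  fx <- coupled_gene_fixture()
  m <- build_pair_matrix(fx$pairs, fx$tsc_links, fx$pac_links, "NM_P1")
  expect_equal(unname(m$o), matrix(c(90L, 10L, 10L, 90L), 2))
  expect_equal(m$N, 200L)
  expect_equal(unname(m$T_i), c(100L, 100L))
  expect_equal(unname(m$P_j), c(100L, 100L))
  # absent gene -> empty matrix
  expect_equal(dim(build_pair_matrix(fx$pairs, fx$tsc_links, fx$pac_links,
                                     "nope")$o), c(0L, 0L))
})

test_that("pair tabulation matches a brute-force cross-tabulation oracle", {
  set.seed(17)
  fx <- coupled_gene_fixture(sample(5:50, 1), sample(5:50, 1),
                             sample(5:50, 1), sample(5:50, 1))
  m <- build_pair_matrix(fx$pairs, fx$tsc_links, fx$pac_links, "NM_P1")
  oracle <- matrix(0L, 2, 2, dimnames = dimnames(m$o))
  for (i in seq_len(nrow(fx$pairs))) {
    oracle[fx$pairs$tsc_id[i], fx$pairs$pac_id[i]] <-
      oracle[fx$pairs$tsc_id[i], fx$pairs$pac_id[i]] + 1L
  }
  expect_equal(m$o, oracle)
  expect_equal(sum(m$o), m$N)
})

test_that("independence p-values follow the Poisson contingency null", {
  fx <- coupled_gene_fixture()
  m <- build_pair_matrix(fx$pairs, fx$tsc_links, fx$pac_links, "NM_P1")
  cells <- pair_independence_pvalue(m)
  d <- cells[cells$o == 90, ][1, ]
  expect_equal(d$e, 50)
  expect_equal(d$p_value, pois_tail_oracle(90, 50), tolerance = 1e-12)
  # expected counts sum to N exactly
  expect_equal(sum(cells$e), m$N)
  # zero cell -> p = 1
  m0 <- m; m0$o[1, 2] <- 0L
  m0$T_i <- rowSums(m0$o); m0$P_j <- colSums(m0$o); m0$N <- sum(m0$o)
  expect_equal(pair_independence_pvalue(m0)$p_value[
    pair_independence_pvalue(m0)$o == 0], 1)
})

test_that("a perfectly proportional matrix is never significant", {
  m <- structure(list(gene_id = "g",
                      o = matrix(c(25L, 25L, 25L, 25L), 2,
                                 dimnames = list(c("t1", "t2"),
                                                 c("p1", "p2")))),
                 class = "pair_matrix")
  m$T_i <- rowSums(m$o); m$P_j <- colSums(m$o); m$N <- sum(m$o)
  expect_true(all(pair_independence_pvalue(m)$p_value >= 0.4))
})

test_that("single-cell matrices get p = 1 by convention", {
  m <- structure(list(gene_id = "g",
                      o = matrix(30L, 1, 1,
                                 dimnames = list("t", "p"))),
                 class = "pair_matrix")
  m$T_i <- rowSums(m$o); m$P_j <- colSums(m$o); m$N <- sum(m$o)
  expect_equal(pair_independence_pvalue(m)$p_value, 1)
})

test_that("preferred selection applies all four criteria strictly", {
  fx <- coupled_gene_fixture()
  m <- build_pair_matrix(fx$pairs, fx$tsc_links, fx$pac_links, "NM_P1")
  sel <- select_preferred(m, pooled_total = 1e6)
  # both diagonal cells: mutual strict maxima, share 0.9, p << 0.05,
  # 90 ppm > 5, 90 tags > 10
  expect_equal(sum(sel$preferred), 2L)
  expect_true(all(sel$o[sel$preferred] == 90))
  # a count of exactly min_tags fails the strict rule
  sel10 <- select_preferred(m, pooled_total = 1e6, min_tags = 90)
  expect_equal(sum(sel10$preferred), 0L)
  # ppm threshold is strict too
  sel_ppm <- select_preferred(m, pooled_total = 90 / 5 * 1e6)
  expect_equal(sum(sel_ppm$preferred), 0L)
  # tied maxima disqualify
  fx_tie <- coupled_gene_fixture(nAX = 50, nBY = 50, nAY = 50, nBX = 50)
  m_tie <- build_pair_matrix(fx_tie$pairs, fx_tie$tsc_links,
                             fx_tie$pac_links, "NM_P1")
  expect_equal(sum(select_preferred(m_tie, 1e6)$preferred), 0L)
})

test_that("unit overlap fraction is the interval Jaccard", {
  expect_equal(unit_overlap_fraction(c(0, 100), c(0, 100)), 1.0)
  expect_equal(unit_overlap_fraction(c(0, 100), c(200, 300)), 0.0)
  expect_equal(unit_overlap_fraction(c(0, 100), c(50, 150)), 1 / 3)
  expect_equal(unit_overlap_fraction(c(0, 100), c(50, 150),
                                     method = "shorter"), 0.5)
  expect_error(unit_overlap_fraction(c(5, 5), c(0, 10)), "degenerate")
})

test_that("tissue Z-scores satisfy the standardisation identities", {
  libs <- sprintf("t%02d", 1:18)
  flat <- tissue_zscores(setNames(rep(3, 18), libs))
  expect_equal(unname(flat$z), rep(0, 18))
  set.seed(51)
  v <- setNames(rexp(18) * 10, libs)
  z <- tissue_zscores(v)
  expect_equal(mean(z$z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z$z^2)), 1, tolerance = 1e-12)
  # hand moment calculation for a single spiked tissue
  sp <- setNames(c(rep(3, 17), 300), libs)
  x <- log2(sp + 1)
  mu <- mean(x); sig <- sqrt(mean((x - mu)^2))
  expect_equal(unname(tissue_zscores(sp)$z[18]), (x[[18]] - mu) / sig,
               tolerance = 1e-12)
  expect_error(tissue_zscores(c(a = 1)), ">= 2 libraries")
})

test_that("switching detection pairs the tissues above the Z cut", {
  libs <- c("brain", "testis", "liver", "heart")
  zA <- list(z = setNames(c(3.3, -1, -1, -1.3), libs))
  zB <- list(z = setNames(c(-1, 2.8, -0.9, -0.9), libs))
  sw <- detect_switching_pairs(zA, zB)
  expect_equal(sw, data.frame(tissue_a = "brain", tissue_b = "testis"))
  flat <- list(z = setNames(rep(0, 4), libs))
  expect_equal(nrow(detect_switching_pairs(flat, flat)), 0L)
  expect_equal(nrow(detect_switching_pairs(zA, zB, z_cut = Inf)), 0L)
})

test_that("connected units require strand, gap and ppm rules", {
  # gene A [10000, 15000) +, gene B [55000, 60000) +, 40-kb gap
  mk_gene <- function(id, s, e, strand) {
    g <- data.frame(gene_id = id, chrom = "chrC", strand = strand,
                    tx_start = s, tx_end = e, coding_class = "NM",
                    stringsAsFactors = FALSE)
    g$exon_starts <- list(c(s, e - 1000L))
    g$exon_ends <- list(c(s + 1000L, e))
    g
  }
  genes <- rbind(mk_gene("NM_A", 10000L, 15000L, "+"),
                 mk_gene("NM_B", 55000L, 60000L, "+"))
  p5 <- rep(10000L, 8); p3 <- rep(59999L, 8)
  pairs <- make_pairs("chrC", p5, "+", "chrC", p3, "+")
  tscs <- clusters_from_positions("chrC", p5, "+", kind = "TSC")
  pacs <- clusters_from_positions("chrC", p3, "+", kind = "PAC")
  pairs <- assign_pairs_to_clusters(pairs, tscs, pacs)
  tl <- associate_clusters(tscs, genes)
  pl <- associate_clusters(pacs, genes)
  cu <- find_connected_units(pairs, genes, tl, pl, pooled_total = 1e6)
  expect_equal(nrow(cu), 1L)
  expect_equal(cu$gene5, "NM_A")
  expect_equal(cu$gene3, "NM_B")
  expect_equal(cu$gap, 40000L)
  # 4 ppm -> below the strict threshold
  expect_equal(nrow(find_connected_units(pairs, genes, tl, pl,
                                         pooled_total = 2e6)), 0L)
  # opposite strands -> never connected
  genesX <- genes; genesX$strand[2] <- "-"
  plX <- associate_clusters(
    clusters_from_positions("chrC", p3, "-", kind = "PAC"), genesX)
  pairsX <- assign_pairs_to_clusters(
    make_pairs("chrC", p5, "+", "chrC", 55000L, "-"),
    tscs, clusters_from_positions("chrC", 55000L, "-", kind = "PAC"))
  expect_equal(nrow(find_connected_units(pairsX, genesX, tl, plX,
                                         pooled_total = 1e6)), 0L)
})

test_that("hypergeometric enrichment filters term sizes and matches oracle", {
  bg <- sprintf("g%04d", 1:1000)
  fg <- bg[1:50]
  t2g <- rbind(
    data.frame(term = "small", gene = bg[1:99]),
    data.frame(term = "ok", gene = bg[c(1:40, 101:200)]),
    data.frame(term = "big", gene = bg[1:501])
  )
  res <- geneset_enrichment(fg, bg, t2g)
  expect_equal(res$term, "ok")
  expect_equal(res$k, 40L)
  expect_equal(res$p_value, hyper_tail_oracle(40, 140, 50, 1000),
               tolerance = 1e-12)
  # k = 0 -> p = 1
  t2g0 <- data.frame(term = "none", gene = bg[501:700])
  expect_equal(geneset_enrichment(fg, bg, t2g0)$p_value, 1)
  expect_error(geneset_enrichment(c("zz"), bg, t2g), "subset")
  # random small instances against the summation oracle
  set.seed(61)
  for (i in 1:50) {
    N <- sample(100:300, 1)
    bgx <- sprintf("x%04d", seq_len(N))
    n <- sample(10:60, 1)
    K <- sample(5:80, 1)
    fgx <- sample(bgx, n)
    t2gx <- data.frame(term = "t", gene = sample(bgx, K))
    r <- geneset_enrichment(fgx, bgx, t2gx, size_min = 1, size_max = N)
    k <- sum(fgx %in% t2gx$gene)
    expect_equal(r$p_value, hyper_tail_oracle(k, K, n, N),
                 tolerance = 1e-12)
  }
})
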