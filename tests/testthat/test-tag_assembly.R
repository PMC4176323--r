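test_that("full single-block coverage gives one exon at integrity 1", {
  tags <- data.frame(pos = 499L, strand = "+",
                     blocks_sizes = "500", blocks_starts = "0")
  m <- assemble_region(tags, c(0L, 500L))
  expect_equal(m$integrity, 1.0)
  expect_equal(m$assembled_length, 500L)
  expect_equal(unname(m$exons[, 1]), 0L)
  expect_equal(unname(m$exons[, 2]), 500L)
  expect_equal(nrow(m$introns), 0L)
})

test_that("split tags label their gaps as introns", {
  tags <- data.frame(pos = 499L, strand = "+",
                     blocks_sizes = "200,200", blocks_starts = "0,300")
  m <- assemble_region(tags, c(0L, 500L))
  expect_equal(m$integrity, 1.0)
  expect_equal(m$exons, cbind(start = c(0L, 300L), end = c(200L, 500L)))
  expect_equal(m$introns, cbind(start = 200L, end = 300L))
  expect_equal(m$assembled_length, 400L)
})

test_that("uncovered unspanned coordinates lower integrity", {
  tags <- data.frame(pos = c(399L, 499L), strand = "+",
                     blocks_sizes = c("400", "50"),
                     blocks_starts = c("0", "0"))
  m <- assemble_region(tags, c(0L, 500L))
  expect_equal(m$integrity, 450 / 500)
  expect_equal(sum(m$labels == "unknown"), 50L)
  expect_error(assemble_region(tags, c(100L, 100L)), "empty")
})

test_that("direct coverage beats a conflicting splice gap", {
  tags <- data.frame(pos = c(499L, 249L), strand = "+",
                     blocks_sizes = c("100,100", "100"),
                     blocks_starts = c("0,400", "0"))
  m <- assemble_region(tags, c(0L, 500L))
  # the second tag covers [150,250) inside the first tag's gap [100,400)
  expect_equal(unname(m$exons),
               unname(cbind(c(0L, 150L, 400L), c(100L, 250L, 500L))))
  expect_true(all(m$labels[101:150] == "intron"))
  expect_true(all(m$labels[151:250] == "transcript"))
})

test_that("minus-strand block anchoring mirrors the plus strand", {
  tags <- data.frame(pos = 0L, strand = "-",
                     blocks_sizes = "200,200", blocks_starts = "0,300")
  m <- assemble_region(tags, c(0L, 500L))
  expect_equal(m$exons, cbind(start = c(0L, 300L), end = c(200L, 500L)))
})

test_that("integrity is monotone under added evidence", {
  set.seed(77)
  for (rep in seq_len(200)) {
    L <- sample(50:300, 1)
    mk_tag <- function() {
      a <- sample(0:(L - 10), 1)
      w <- sample(5:40, 1)
      if (runif(1) < 0.5) {
        data.frame(pos = a + w - 1L, strand = "+",
                   blocks_sizes = as.character(w),
                   blocks_starts = "0")
      } else {
        w2 <- sample(5:30, 1); gap <- sample(5:50, 1)
        data.frame(pos = a + w + gap + w2 - 1L, strand = "+",
                   blocks_sizes = paste(w, w2, sep = ","),
                   blocks_starts = paste(0L, w + gap, sep = ","))
      }
    }
    t1 <- do.call(rbind, replicate(sample(1:4, 1), mk_tag(),
                                   simplify = FALSE))
    t2 <- do.call(rbind, replicate(sample(1:4, 1), mk_tag(),
                                   simplify = FALSE))
    m1 <- assemble_region(t1, c(0L, L))
    m12 <- assemble_region(rbind(t1, t2), c(0L, L))
    m2 <- assemble_region(t2, c(0L, L))
    expect_gte(m12$integrity, max(m1$integrity, m2$integrity))
    # adding evidence never unlabels a coordinate
    expect_true(all(m12$labels[m1$labels == "transcript"] == "transcript"))
    expect_true(all(m12$labels[m1$labels != "unknown"] != "unknown"))
  }
})

test_that("exhaustive tiling recovers exon/intron structure base-exactly", {
  cfg <- sim_config(seed = 12, n_genes = 10, depth = 10,
                    alt_tsc_prob = 0, alt_pac_prob = 0)
  ann <- simulate_annotation(cfg)
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    tags <- tiling_random_tags(g, span = 80L, step = 40L)
    region <- c(g$tx_start, g$tx_end)
    m <- assemble_region(
      data.frame(pos = tags$pos3, strand = tags$strand3,
                 blocks_sizes = tags$blocks3_sizes,
                 blocks_starts = tags$blocks3_starts),
      region)
    expect_equal(m$integrity, 1.0)
    expect_equal(unname(m$exons[, 1]), g$exon_starts[[1]])
    expect_equal(unname(m$exons[, 2]), g$exon_ends[[1]])
  }
})

test_that("assembly report applies the strict coverage cut", {
  mk_model <- function(int) {
    n_cov <- round(int * 100)
    tags <- if (n_cov > 0) {
      data.frame(pos = n_cov - 1L, strand = "+",
                 blocks_sizes = as.character(n_cov), blocks_starts = "0")
    } else {
      data.frame(pos = 0L, strand = "+", blocks_sizes = "1",
                 blocks_starts = "0")
    }
    assemble_region(tags, c(0L, 100L))
  }
  models <- lapply(c(0.95, 0.96, 1.0, 0.5), mk_model)
  rep1 <- assembly_report(models, coverage_cut = 0.95)
  expect_equal(rep1$n_models, 4L)
  expect_equal(rep1$n_assembled, 2L)  # 0.95 exactly is excluded
  set.seed(78)
  ints <- sample(50:100, 100, TRUE) / 100
  models2 <- lapply(ints, mk_model)
  rep2 <- assembly_report(models2, coverage_cut = 0.9)
  expect_equal(rep2$n_assembled, sum(vapply(models2, `[[`, 0,
                                            "integrity") > 0.9))
})

test_that("TSS-to-tag distances are measured in mRNA coordinates", {
  # one 10-kb intron between two exons; exonic separation 800
  g <- data.frame(gene_id = "NM_D1", chrom = "chrD", strand = "+",
                  tx_start = 0L, tx_end = 11000L, coding_class = "NM",
                  stringsAsFactors = FALSE)
  g$exon_starts <- list(c(0L, 10500L))
  g$exon_ends <- list(c(500L, 11000L))
  # mRNA offset 800 = genomic 10500 + 300
  pairs <- make_pairs("chrD", 0L, "+", "chrD", 10800L, "+",
                      end3_kind = "RANDOM")
  stats <- data.frame(library_id = "libA", total_pairs = 1L,
                      fraction_label = "dR1.0")
  d <- size_fraction_distance_check(pairs, g, stats)
  expect_equal(d$distances$distance, 800L)
  expect_equal(d$n_skipped, 0L)
  # a pair outside any model is skipped with a count
  off <- make_pairs("chrD", 20000L, "+", "chrD", 21000L, "+",
                    end3_kind = "RANDOM")
  d2 <- size_fraction_distance_check(off, g, stats)
  expect_equal(d2$n_skipped, 1L)
  expect_equal(nrow(d2$distances), 0L)
})

test_that("simulated size fractions bound the mRNA distances", {
  cfg <- sim_config(seed = 13, n_genes = 12, depth = 10, n_libraries = 2,
                    emit_random = TRUE, depth_random = 400,
                    truncation_rate = 0, chimera_rate = 0,
                    internal_priming_rate = 0, fusions = NA)
  sim <- simulate_dataset(cfg)
  rnd <- sim$pairs[sim$pairs$end3_kind == "RANDOM", ]
  d <- size_fraction_distance_check(rnd, sim$genes, sim$stats)
  dist <- d$distances
  for (fr in unique(dist$fraction_label)) {
    b <- cfg$random_fractions[[fr]]
    dd <- dist$distance[dist$fraction_label == fr]
    # inserts are capped at the mRNA length, so distances never exceed
    # the fraction's upper bound
    expect_true(all(dd <= b[2] - 1L))
  }
  # the shortest fraction is never capped (every mRNA is > 1 kb here), so
  # its distances fall inside the insert-length window
  d05 <- dist$distance[dist$fraction_label == "dR0.5"]
  expect_true(all(d05 >= cfg$random_fractions[["dR0.5"]][1] - 1L))
  expect_equal(d$n_skipped, 0L)
})
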