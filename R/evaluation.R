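# Self-validation experiments: each function simulates a data set under
# stated study conditions, runs the corresponding analysis stage, and
# returns the measured operating characteristics. Problem sizes are chosen
# so each experiment finishes in seconds to a few minutes on one CPU while
# keeping per-unit tag depths in the regime the method assumes (see the
# methods vignette).

.planted_cluster_id <- function(kind, genes, g, pos) {
  paste(kind, genes$chrom[g], genes$strand[g], pos %/% 500L, sep = ":")
}

#' Null calibration of the pair-independence test
#'
#' Simulates genes whose TSS and PAS are selected independently (no
#' planted coupling, no noise), builds the per-gene TSC x PAC matrices
#' through the pipeline, and evaluates the Poisson upper-tail p-value of
#' every cell at the expectation known from the generative site weights.
#' Under this null the tail probability is calibrated, so about 5% of
#' cells fall below 0.05 (slightly fewer, because counts are discrete).
#' With the expectation re-estimated from the observed marginals the test
#' is deliberately conservative; that rate is returned alongside.
#'
#' @param seed RNG seed.
#' @param n_genes,depth Simulation size (defaults 200 genes, 12000 pairs
#'   per library over 18 libraries, keeping even the smallest cell
#'   expectations above ~5 so discreteness barely bites).
#' @return List with `flag_rate` (fraction of cells with p < 0.05 at the
#'   generative expectation), `flag_rate_estimated` (same with marginal
#'   estimates), `n_cells`.
#' @export
eval_independence_calibration <- function(seed, n_genes = 200,
                                          depth = 12000) {
  cfg <- sim_config(seed = seed, n_genes = n_genes, depth = depth,
                    n_libraries = 18, alt_tsc_prob = 1, alt_pac_prob = 1,
                    preferred_fraction = 0, truncation_rate = 0,
                    internal_priming_rate = 0, chimera_rate = 0,
                    expr_base_sd = 0.5, tissue_bias_sd = 0.5, fusions = NA)
  sim <- simulate_dataset(cfg)
  res <- run_end_pipeline(sim$pairs, sim$stats, sim$genes)
  tr <- sim$truth
  # generative expectation of each gene's pooled pair count: per library,
  # depth times the gene's expression share; cells then behave as
  # independent Poisson counts around E
  gene_expect <- as.numeric(tr$expr_w %*%
                              (cfg$depth / colSums(tr$expr_w)))
  cells <- .pair_cell_counts(res$pairs)
  p_true <- c(); p_est <- c()
  for (g in seq_len(n_genes)) {
    m <- build_pair_matrix(res$pairs, res$tsc_links, res$pac_links,
                           sim$genes$gene_id[g], cells = cells)
    if (m$N == 0L || length(m$o) < 2L) next
    ti <- match(rownames(m$o), .planted_cluster_id(
      "TSC", sim$genes, g, tr$tss_pos[g, seq_len(tr$n_tss[g])]))
    pj <- match(colnames(m$o), .planted_cluster_id(
      "PAC", sim$genes, g, tr$pas_pos[g, seq_len(tr$n_pas[g])]))
    if (anyNA(ti) || anyNA(pj)) next
    tw <- tr$tss_w[g, ti]; pw <- tr$pas_w[g, pj]
    E <- gene_expect[g] * outer(tw / sum(tw), pw / sum(pw))
    dimnames(E) <- dimnames(m$o)
    p_true <- c(p_true, pair_independence_pvalue(m, expected = E)$p_value)
    p_est <- c(p_est, pair_independence_pvalue(m)$p_value)
  }
  list(flag_rate = mean(p_true < 0.05),
       flag_rate_estimated = mean(p_est < 0.05),
       n_cells = length(p_true))
}

#' Recovery of planted preferred TSC-PAC couplings
#'
#' Simulates genes with alternative TSCs/PACs, half of them given a
#' planted coupling at share 0.9, with the standard noise sources (5%
#' truncation, 1% internal priming, 1% chimeras), and runs preferred-pair
#' selection. Library depth is set so every planted unit carries well over
#' 50 supporting pairs.
#'
#' @param seed RNG seed.
#' @param n_genes,depth Simulation size (defaults 200 genes, 16000 pairs
#'   per library over 18 libraries).
#' @return List with `recall` (planted couplings flagged preferred),
#'   `fpr` (non-planted cells flagged), `n_planted`, `n_cells`.
#' @export
eval_preferred_recovery <- function(seed, n_genes = 200, depth = 16000) {
  cfg <- sim_config(seed = seed, n_genes = n_genes, depth = depth,
                    n_libraries = 18, alt_tsc_prob = 1, alt_pac_prob = 1,
                    preferred_fraction = 0.5, coupling_share = 0.9,
                    expr_base_sd = 0.5, tissue_bias_sd = 0.5, fusions = NA)
  sim <- simulate_dataset(cfg)
  res <- run_end_pipeline(sim$pairs, sim$stats, sim$genes)
  tr <- sim$truth
  planted <- unlist(lapply(which(tr$preferred), function(g) {
    vapply(seq_len(tr$n_tss[g]), function(k) {
      paste(sim$genes$gene_id[g],
            .planted_cluster_id("TSC", sim$genes, g, tr$tss_pos[g, k]),
            .planted_cluster_id("PAC", sim$genes, g,
                                tr$pas_pos[g, tr$sigma[g, k]]))
    }, "")
  }))
  cells <- res$cells
  key <- paste(cells$gene_id, cells$tsc_id, cells$pac_id)
  called <- key[cells$preferred]
  list(recall = mean(planted %in% called),
       fpr = if (sum(!key %in% planted) > 0)
         sum(cells$preferred & !key %in% planted) /
         sum(!key %in% planted) else 0,
       n_planted = length(planted),
       n_cells = nrow(cells))
}

#' Poisson screening of planted TSCs against truncation noise
#'
#' Simulates single-TSC genes with 5% truncated (cap-replacement-failure)
#' TSS tags scattered along the mRNA and asks, per gene, whether the
#' planted 500-bp bin is significantly overloaded relative to a uniform
#' Poisson scatter of all the gene's TSS tags along its mRNA.
#'
#' @param seed RNG seed.
#' @param n_genes,depth Simulation size (defaults 100 genes, 2000 pairs
#'   per library over 18 libraries).
#' @param p_cut Significance threshold (default 1e-10).
#' @return List with `frac_significant`, `n_genes`, `min_tags` (smallest
#'   per-gene tag total, for reference).
#' @export
eval_cluster_screening <- function(seed, n_genes = 100, depth = 2000,
                                   p_cut = 1e-10) {
  cfg <- sim_config(seed = seed, n_genes = n_genes, depth = depth,
                    n_libraries = 18, alt_tsc_prob = 0, alt_pac_prob = 0,
                    truncation_rate = 0.05, internal_priming_rate = 0,
                    chimera_rate = 0, expr_base_sd = 0.5,
                    tissue_bias_sd = 0.5, fusions = NA)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth
  g <- sim$truth_tags$gene5
  bin_hit <- sim$pairs$pos5 %/% 500L == tr$tss_pos[g, 1L] %/% 500L
  N <- tabulate(g, n_genes)
  k <- tabulate(g[bin_hit], n_genes)
  p <- cluster_poisson_pvalue(k, N, tr$mrna_len)$p_value
  list(frac_significant = mean(p < p_cut), n_genes = n_genes,
       min_tags = min(N))
}

#' Fusion recovery and false-call replicates
#'
#' For each replicate seed, simulates four cancer-cell-line-like libraries
#' over 500 genes on two chromosomes with 1% random chimeric re-pairing
#' and two planted fusions at 10 ppm (one inter-chromosomal, one
#' same-chromosome far beyond 3 Mb), then runs clustering, gene
#' association and fusion detection. Chimeric pairs scatter thinly over
#' gene pairs and must never exceed the 5-ppm support threshold.
#'
#' @param seed Base RNG seed; replicate r uses `seed + 7919 * r`.
#' @param n_reps Number of replicates (default 20).
#' @param n_genes,depth,n_libraries Per-replicate simulation size.
#' @return List with `recovered_reps` (replicates recovering both planted
#'   fusions), `false_calls` (non-planted candidates over all
#'   replicates), `n_reps`.
#' @export
eval_fusion_replicates <- function(seed, n_reps = 20, n_genes = 500,
                                   depth = 200000, n_libraries = 4) {
  recovered <- 0L; false_calls <- 0L
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(seed = seed + 7919L * r, n_genes = n_genes,
                      depth = depth, n_libraries = n_libraries,
                      alt_tsc_prob = 0, alt_pac_prob = 0,
                      preferred_fraction = 0, truncation_rate = 0,
                      internal_priming_rate = 0, chimera_rate = 0.01,
                      expr_base_sd = 0.2, tissue_bias_sd = 0.2,
                      fusions = data.frame(gene5 = c(1L, 2L),
                                           gene3 = c(n_genes, 100L),
                                           ppm = 10))
    sim <- simulate_dataset(cfg)
    lib_sizes <- stats::setNames(sim$stats$total_pairs,
                                 sim$stats$library_id)
    libs <- sort(sim$stats$library_id)
    tscs <- filter_clusters(compute_ppm(cluster_tags(
      data.frame(chrom = sim$pairs$chrom5, pos = sim$pairs$pos5,
                 strand = sim$pairs$strand5,
                 library_id = sim$pairs$library_id),
      "TSC", libraries = libs), lib_sizes), 5)
    pacs <- filter_clusters(compute_ppm(cluster_tags(
      data.frame(chrom = sim$pairs$chrom3, pos = sim$pairs$pos3,
                 strand = sim$pairs$strand3,
                 library_id = sim$pairs$library_id),
      "PAC", libraries = libs), lib_sizes), 5)
    pr <- assign_pairs_to_clusters(sim$pairs, tscs, pacs)
    fus <- detect_fusions(pr, sim$genes,
                          associate_clusters(tscs, sim$genes),
                          associate_clusters(pacs, sim$genes),
                          sum(lib_sizes))
    planted <- paste(sim$genes$gene_id[c(1L, 2L)],
                     sim$genes$gene_id[c(n_genes, 100L)])
    got <- paste(fus$gene5, fus$gene3)
    if (all(planted %in% got)) recovered <- recovered + 1L
    false_calls <- false_calls + sum(!got %in% planted)
  }
  list(recovered_reps = recovered, false_calls = false_calls,
       n_reps = n_reps)
}

#' Exact assembly under exhaustive noiseless coverage
#'
#' Tiles each simulated gene's mRNA exhaustively with exact split tags and
#' asserts that assembly reproduces the exon/intron structure base-exactly
#' at integrity 1; also counts violations of integrity monotonicity over
#' random tag-set pairs.
#'
#' @param seed RNG seed.
#' @param n_genes Genes to tile (default 20).
#' @param n_monotone Random instances for the monotonicity check
#'   (default 1000).
#' @return List with `exact_rate`, `mean_integrity`,
#'   `monotone_violations`, `n_genes`, `n_monotone`.
#' @export
eval_assembly_exact <- function(seed, n_genes = 20, n_monotone = 1000) {
  cfg <- sim_config(seed = seed, n_genes = n_genes, depth = 10,
                    alt_tsc_prob = 0, alt_pac_prob = 0)
  ann <- simulate_annotation(cfg)
  exact <- logical(n_genes); integ <- numeric(n_genes)
  for (i in seq_len(n_genes)) {
    g <- ann$genes[i, ]
    tags <- tiling_random_tags(g, span = 80L, step = 40L)
    m <- assemble_region(
      data.frame(pos = tags$pos3, strand = tags$strand3,
                 blocks_sizes = tags$blocks3_sizes,
                 blocks_starts = tags$blocks3_starts),
      c(g$tx_start, g$tx_end))
    integ[i] <- m$integrity
    exact[i] <- m$integrity == 1 &&
      identical(unname(m$exons[, 1]), g$exon_starts[[1]]) &&
      identical(unname(m$exons[, 2]), g$exon_ends[[1]])
  }
  set.seed(seed + 1L)
  viol <- 0L
  for (r in seq_len(n_monotone)) {
    L <- sample(50:300, 1)
    mk <- function() {
      a <- sample(0:(L - 10L), 1)
      w <- sample(5:40, 1)
      if (stats::runif(1) < 0.5) {
        data.frame(pos = a + w - 1L, strand = "+",
                   blocks_sizes = as.character(w), blocks_starts = "0")
      } else {
        w2 <- sample(5:30, 1); gap <- sample(5:50, 1)
        data.frame(pos = a + w + gap + w2 - 1L, strand = "+",
                   blocks_sizes = paste(w, w2, sep = ","),
                   blocks_starts = paste(0L, w + gap, sep = ","))
      }
    }
    t1 <- mk(); t2 <- mk()
    i1 <- assemble_region(t1, c(0L, L))$integrity
    i12 <- assemble_region(rbind(t1, t2), c(0L, L))$integrity
    if (i12 < i1 - 1e-12) viol <- viol + 1L
  }
  list(exact_rate = mean(exact), mean_integrity = mean(integ),
       monotone_violations = viol, n_genes = n_genes,
       n_monotone = n_monotone)
}

#' Z-score standardisation identities on simulated units
#'
#' Computes tissue Z-scores for every simulated cluster and measures the
#' worst deviation from the exact identities mean(z) = 0 and sd(z) = 1
#' (population) for non-constant units; constant units must give z = 0.
#'
#' @param seed RNG seed.
#' @param n_genes,depth Simulation size.
#' @return List with `max_mean_dev`, `max_sd_dev`, `n_units`,
#'   `constant_ok`.
#' @export
eval_zscore_identities <- function(seed, n_genes = 60, depth = 5000) {
  cfg <- sim_config(seed = seed, n_genes = n_genes, depth = depth,
                    n_libraries = 18, fusions = NA)
  sim <- simulate_dataset(cfg)
  res <- run_end_pipeline(sim$pairs, sim$stats, sim$genes)
  cl <- rbind(res$tscs["cluster_id"], res$pacs["cluster_id"])
  ppm <- rbind(res$tscs$ppm, res$pacs$ppm)
  mean_dev <- 0; sd_dev <- 0; n <- 0L; const_ok <- TRUE
  for (i in seq_len(nrow(ppm))) {
    z <- tissue_zscores(ppm[i, ])
    if (z$sigma > 0) {
      mean_dev <- max(mean_dev, abs(mean(z$z)))
      sd_dev <- max(sd_dev, abs(sqrt(mean(z$z^2)) - 1))
      n <- n + 1L
    } else if (any(z$z != 0)) {
      const_ok <- FALSE
    }
  }
  list(max_mean_dev = mean_dev, max_sd_dev = sd_dev, n_units = n,
       constant_ok = const_ok)
}

#' Byte-level determinism of the synthetic pipeline
#'
#' Runs the full generator twice with one configuration and compares every
#' emitted file byte for byte.
#'
#' @param seed RNG seed.
#' @return List with `identical` (logical) and `n_files`.
#' @export
eval_determinism <- function(seed) {
  cfg <- sim_config(seed = seed, n_genes = 15, depth = 500,
                    n_libraries = 4, emit_genome = TRUE,
                    emit_random = TRUE, depth_random = 200)
  d1 <- tempfile("sim1_"); d2 <- tempfile("sim2_")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  write_simulation(simulate_dataset(cfg), d1)
  write_simulation(simulate_dataset(cfg), d2)
  files <- sort(list.files(d1))
  same <- identical(files, sort(list.files(d2))) &&
    all(vapply(files, function(f) {
      identical(readBin(file.path(d1, f), "raw", 1e8),
                readBin(file.path(d2, f), "raw", 1e8))
    }, FALSE))
  list(identical = same, n_files = length(files))
}
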