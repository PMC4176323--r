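.TISSUES <- c("adipose", "brain", "breast", "colon", "heart", "kidney",
              "liver", "lung", "lymph_node", "ovary", "prostate",
              "skeletal_muscle", "testis", "thyroid",
              "HeLa", "HEK293", "DLD1", "MCF7")

#' Configuration of the synthetic mate-pair tag study
#'
#' Bundles every knob of the generator. The defaults emulate the design the
#' analysis assumes: 18 independently sequenced oligo-dT libraries (14
#' tissues, 4 cell lines), genes with up to three alternative TSSs/PASs in
#' distinct 500-bp bins, a subset of genes with a preferred TSC-PAC
#' coupling at share 0.9, log-normal tissue-biased expression, and the
#' three library-construction noise sources: 5' truncation (failed cap
#' replacement) placing the TSS tag uniformly inside the mRNA, internal
#' oligo-dT priming placing the PAS tag at a genomic A-run, and random
#' chimeric re-pairing of ends at the ligation step.
#'
#' @param seed Integer RNG seed; identical configurations are byte-identical.
#' @param n_genes Number of genes (split over 2 chromosomes so
#'   inter-chromosomal fusions are plantable).
#' @param n_libraries Number of oligo-dT (TSS-PAS) libraries (default 18).
#' @param depth Mate pairs drawn per dT library (default 50000).
#' @param exons_per_gene,exon_length,intron_length Integer ranges.
#' @param gene_spacing Genomic slot per gene in bp (default 120000; keeps
#'   50-kb association windows of neighbouring genes clean).
#' @param alt_tsc_prob,alt_pac_prob Per-extra-site probability; each gene
#'   has `1 + Binomial(2, p)` TSSs/PASs.
#' @param preferred_fraction Fraction of genes with >= 2 TSSs and >= 2 PASs
#'   given a planted TSC-PAC coupling.
#' @param coupling_share Probability `s` that a tag from a preferred gene
#'   uses the coupled PAC of its TSS (default 0.9).
#' @param expr_base_sd SD of per-gene baseline log2 abundance (default 1.5).
#'   At desk-scale gene counts a large value concentrates library share on
#'   few genes; lower it to emulate the flat per-gene shares of a full
#'   transcriptome.
#' @param tissue_bias_sd SD of per-library log2 expression deviations.
#' @param tissue_specific_fraction,tissue_boost Fraction of genes boosted
#'   by `tissue_boost` log2 units in one random library (exercises Z > 2).
#' @param truncation_rate,internal_priming_rate,chimera_rate Noise rates.
#' @param fusions `data.frame(gene5, gene3, ppm)` of planted fusions (gene
#'   indices), or `NULL` for the default two plantings (one
#'   inter-chromosomal, one same-chromosome > 3 Mb apart) at 10 ppm, or
#'   `NA` for none.
#' @param emit_random Also emit the three TSS/Random size-fraction
#'   libraries.
#' @param random_fractions Named list of insert-length bounds in nt.
#' @param depth_random Pairs per dR library (default `depth`).
#' @param random_tag_span mRNA bp covered by a random 3' tag (default 100).
#' @param emit_genome Generate the genome sequence with planted motifs
#'   (AATAAA, TATA, A-runs); turn off when only tag tables are needed.
#' @param polya_signal_prob Probability a PAS has a planted AATAAA at -21.
#' @param tata_prob Probability a TSS has a planted TATA box at -29.
#' @param cpg_prob Probability a TSS gets a CpG-island interval.
#' @param nr_fraction Fraction of genes labelled NR (non-coding).
#' @param mapq_low_rate Fraction of tag ends given a low mapping quality
#'   (uniform 0-30); the rest get 60.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 120L,
                       n_libraries = 18L,
                       depth = 50000L,
                       exons_per_gene = c(4L, 8L),
                       exon_length = c(300L, 600L),
                       intron_length = c(200L, 2000L),
                       gene_spacing = 120000L,
                       alt_tsc_prob = 0.3,
                       alt_pac_prob = 0.3,
                       preferred_fraction = 0.3,
                       coupling_share = 0.9,
                       expr_base_sd = 1.5,
                       tissue_bias_sd = 1,
                       tissue_specific_fraction = 0.1,
                       tissue_boost = 3,
                       truncation_rate = 0.05,
                       internal_priming_rate = 0.01,
                       chimera_rate = 0.01,
                       fusions = NULL,
                       emit_random = FALSE,
                       random_fractions = list("dR0.5" = c(500L, 1000L),
                                               "dR1.0" = c(1000L, 2000L),
                                               "dR2.0" = c(2000L, 5000L)),
                       depth_random = NULL,
                       random_tag_span = 100L,
                       emit_genome = FALSE,
                       polya_signal_prob = 0.72,
                       tata_prob = 0.15,
                       cpg_prob = 0.6,
                       nr_fraction = 0.1,
                       mapq_low_rate = 0.02) {
  cfg <- as.list(environment())
  cfg$depth_random <- depth_random %||% depth
  probs <- c(alt_tsc_prob, alt_pac_prob, preferred_fraction, coupling_share,
             truncation_rate, internal_priming_rate, chimera_rate,
             polya_signal_prob, tata_prob, cpg_prob, nr_fraction,
             mapq_low_rate, tissue_specific_fraction)
  stopifnot(all(probs >= 0 & probs <= 1), depth > 0, n_genes > 0,
            n_libraries >= 2, coupling_share >= 0.5)
  class(cfg) <- "sim_config"
  cfg
}

.lib_names <- function(n) {
  if (n <= length(.TISSUES)) return(.TISSUES[seq_len(n)])
  c(.TISSUES, sprintf("lib%02d", seq_len(n - length(.TISSUES))))
}

.runif_int <- function(n, range) {
  if (range[1] == range[2]) rep.int(range[1], n) else
    as.integer(range[1] + floor(stats::runif(n) * (range[2] - range[1] + 1L)))
}

#' Simulate a synthetic annotation (genes, end sites, genome)
#'
#' Lays out non-overlapping genes on a two-chromosome assembly, draws exon
#' structures, alternative TSS/PAS positions (alternatives sit in distinct
#' 500-bp bins in the upstream/downstream association windows), the
#' preferred TSC-PAC couplings, the tissue expression matrix, and - when
#' `emit_genome` is set - the genome sequence with AATAAA / TATA / poly(A)
#' run motifs planted at the corresponding sites.
#'
#' @param cfg A [sim_config()].
#' @return A list with `genes` (gene-model table), `truth` (positions,
#'   couplings, expression, planted motifs, fusions) and `genome`
#'   ([Biostrings::DNAStringSet] or `NULL`), plus `cpg` intervals.
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  slots_per_chrom <- as.integer(ceiling(n / 2))
  chrom_len <- slots_per_chrom * cfg$gene_spacing + 10000L
  max_span <- cfg$exons_per_gene[2] * cfg$exon_length[2] +
    (cfg$exons_per_gene[2] - 1L) * cfg$intron_length[2]
  # a slot must hold the gene body plus alternative end sites with enough
  # margin that association windows never reach a neighbour's planted sites
  if (max_span + 66400L > cfg$gene_spacing) {
    stop("gene_spacing too small for the configured gene spans")
  }
  chrom <- ifelse(seq_len(n) <= slots_per_chrom, "chrS1", "chrS2")
  slot <- ifelse(seq_len(n) <= slots_per_chrom, seq_len(n) - 1L,
                 seq_len(n) - slots_per_chrom - 1L)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  is_nr <- stats::runif(n) < cfg$nr_fraction
  gene_id <- ifelse(is_nr, sprintf("NR_S%04d", seq_len(n)),
                    sprintf("NM_S%04d", seq_len(n)))
  exon_starts <- vector("list", n)
  exon_ends <- vector("list", n)
  tx_start <- integer(n); tx_end <- integer(n)
  for (i in seq_len(n)) {
    k <- .runif_int(1L, cfg$exons_per_gene)
    ex_w <- .runif_int(k, cfg$exon_length)
    in_w <- if (k > 1L) .runif_int(k - 1L, cfg$intron_length) else integer(0)
    s0 <- slot[i] * cfg$gene_spacing + 60000L
    st <- s0 + cumsum(c(0L, ex_w[-k] + in_w))
    exon_starts[[i]] <- st
    exon_ends[[i]] <- st + ex_w
    tx_start[i] <- st[1]
    tx_end[i] <- st[k] + ex_w[k]
  }
  genes <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                      tx_start = tx_start, tx_end = tx_end,
                      coding_class = ifelse(is_nr, "NR", "NM"),
                      stringsAsFactors = FALSE)
  genes$exon_starts <- exon_starts
  genes$exon_ends <- exon_ends
  tss0 <- gene_tss(genes); pas0 <- gene_pas(genes)
  n_tss <- 1L + stats::rbinom(n, 2L, cfg$alt_tsc_prob)
  n_pas <- 1L + stats::rbinom(n, 2L, cfg$alt_pac_prob)
  up <- ifelse(strand == "+", -1L, 1L)
  tss_pos <- cbind(tss0, tss0 + up * 700L, tss0 + up * 1400L)
  pas_pos <- cbind(pas0, pas0 - up * 700L, pas0 - up * 1400L)
  tss_pos[cbind(seq_len(n), 2L)[n_tss < 2L, , drop = FALSE]] <- NA_integer_
  tss_pos[n_tss < 3L, 3L] <- NA_integer_
  pas_pos[cbind(seq_len(n), 2L)[n_pas < 2L, , drop = FALSE]] <- NA_integer_
  pas_pos[n_pas < 3L, 3L] <- NA_integer_
  draw_w <- function(k_vec) {
    w <- matrix(0, n, 3L)
    for (i in seq_len(n)) {
      r <- stats::rexp(k_vec[i]) + 0.25
      w[i, seq_len(k_vec[i])] <- r / sum(r)
    }
    w
  }
  tss_w <- draw_w(n_tss)
  pas_w <- draw_w(n_pas)
  eligible <- n_tss >= 2L & n_pas >= 2L
  preferred <- eligible & stats::runif(n) < cfg$preferred_fraction
  sigma <- matrix(NA_integer_, n, 3L)
  for (i in which(preferred)) {
    m <- min(n_tss[i], n_pas[i])
    perm <- sample.int(n_pas[i], m)
    sigma[i, seq_len(n_tss[i])] <-
      perm[1L + (seq_len(n_tss[i]) - 1L) %% m]
  }
  base <- stats::rnorm(n, 0, cfg$expr_base_sd)
  expr_log2 <- matrix(stats::rnorm(n * cfg$n_libraries, base,
                                   cfg$tissue_bias_sd),
                      n, cfg$n_libraries)
  spec <- stats::runif(n) < cfg$tissue_specific_fraction
  boost_lib <- sample.int(cfg$n_libraries, n, replace = TRUE)
  expr_log2[cbind(which(spec), boost_lib[spec])] <-
    expr_log2[cbind(which(spec), boost_lib[spec])] + cfg$tissue_boost
  expr_w <- 2^expr_log2
  colnames(expr_w) <- .lib_names(cfg$n_libraries)
  arun_pos <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    ex_s <- exon_starts[[i]]
    if (length(ex_s) > 1L) {
      arun_pos[i] <- (exon_ends[[i]][1] + ex_s[2]) %/% 2L
    }
  }
  fus <- cfg$fusions
  if (is.null(fus)) {
    fus <- data.frame(gene5 = integer(0), gene3 = integer(0),
                      ppm = numeric(0))
    if (n >= 4L) {
      fus <- rbind(fus, data.frame(gene5 = 1L, gene3 = n, ppm = 10))
      far <- which(chrom == "chrS1" &
                     abs(tx_start - tx_start[2]) > 3.2e6 &
                     seq_len(n) != 1L)
      if (length(far) > 0L) {
        fus <- rbind(fus, data.frame(gene5 = 2L, gene3 = far[1], ppm = 10))
      }
    }
  } else if (length(fus) == 1L && is.na(fus)) {
    fus <- data.frame(gene5 = integer(0), gene3 = integer(0),
                      ppm = numeric(0))
  }
  has_tata <- stats::runif(n) < cfg$tata_prob
  has_polya_sig <- matrix(stats::runif(n * 3L) < cfg$polya_signal_prob,
                          n, 3L)
  has_cpg <- stats::runif(n) < cfg$cpg_prob
  genome <- NULL
  if (cfg$emit_genome) {
    seqs <- lapply(c(chrS1 = chrom_len, chrS2 = chrom_len), function(len) {
      s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      plant <- function(s, pos0, motif) {
        b <- strsplit(motif, "")[[1]]
        if (pos0 >= 0L && pos0 + length(b) <= len) {
          s[(pos0 + 1L):(pos0 + length(b))] <- b
        }
        s
      }
      attr(s, "plant") <- plant
      s
    })
    plant_sense <- function(ch, pos, strand_i, rel_from, motif) {
      # plant `motif` so that it starts at transcript-relative offset
      # rel_from of `pos` on the sense strand
      if (strand_i == "+") {
        p0 <- pos + rel_from
        m <- motif
      } else {
        m <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(motif)))
        p0 <- pos - rel_from - nchar(motif) + 1L
      }
      b <- strsplit(m, "")[[1]]
      if (p0 >= 0L && p0 + length(b) <= length(seqs[[ch]])) {
        seqs[[ch]][(p0 + 1L):(p0 + length(b))] <<- b
      }
      invisible()
    }
    for (i in seq_len(n)) {
      if (has_tata[i]) {
        plant_sense(chrom[i], tss_pos[i, 1L], strand[i], -29L, "TATAAAAG")
      }
      for (j in seq_len(3L)) {
        if (!is.na(pas_pos[i, j]) && has_polya_sig[i, j]) {
          plant_sense(chrom[i], pas_pos[i, j], strand[i], -21L, "AATAAA")
        }
      }
      if (!is.na(arun_pos[i])) {
        plant_sense(chrom[i], arun_pos[i] - 1L, strand[i], 1L, "AAAAAAAA")
      }
    }
    genome <- Biostrings::DNAStringSet(vapply(seqs, paste, "",
                                              collapse = ""))
  }
  cpg <- data.frame(chrom = chrom[has_cpg],
                    start = pmax(0L, tss_pos[has_cpg, 1L] - 200L),
                    end = tss_pos[has_cpg, 1L] + 200L,
                    stringsAsFactors = FALSE)
  list(
    genes = genes,
    genome = genome,
    cpg = cpg,
    truth = list(
      chrom_len = chrom_len,
      n_tss = n_tss, n_pas = n_pas,
      tss_pos = tss_pos, pas_pos = pas_pos,
      tss_w = tss_w, pas_w = pas_w,
      preferred = preferred, sigma = sigma,
      expr_w = expr_w,
      arun_pos = arun_pos,
      has_tata = has_tata, has_polya_sig = has_polya_sig,
      has_cpg = has_cpg,
      fusions = fus,
      mrna_len = mrna_length(genes)
    )
  )
}

# genomic block matrix of the mRNA interval [a, b) of one gene
.mrna_interval_to_blocks <- function(gene, a, b) {
  ef <- .exon_frame(gene)
  if (gene$strand == "-") {
    tmp <- ef$len - b
    b <- ef$len - a
    a <- tmp
  }
  out <- NULL
  for (i in seq_along(ef$starts)) {
    lo <- max(a, ef$cum[i]); hi <- min(b, ef$cum[i + 1L])
    if (lo < hi) {
      gs <- ef$starts[i] + (lo - ef$cum[i])
      out <- rbind(out, c(gs, gs + (hi - lo)))
    }
  }
  out
}

#' Simulate mate-pair tag tables and the tag-level truth
#'
#' Draws `depth` pairs per dT library: a gene by its library expression
#' weight, a TSS by the gene's site weights, and a PAS either coupled to
#' the TSS (preferred genes, probability `coupling_share`) or by the
#' marginal site weights. Noise is then applied at the configured rates:
#' truncated 5' tags land uniformly on the mRNA, internally primed 3' tags
#' land at the gene's planted A-run, and chimeric rows have their whole 3'
#' ends re-paired at random within the library. Planted fusions contribute
#' `max(1, round(ppm * 1e-6 * depth))` supporting pairs per library at
#' mapping quality 60. With `emit_random`, one TSS/Random library per size
#' fraction is added whose split 3' tags cover the mRNA at the fraction's
#' insert distance from the TSS.
#'
#' @param cfg A [sim_config()].
#' @param ann Annotation from [simulate_annotation()].
#' @return List with `pairs` (ENDPAIR v1 table plus `pair_id`), `stats`
#'   (library totals and fraction labels) and `truth_tags` (`data.frame`
#'   aligned with `pairs`: source gene/TSS/PAS indices and `noise` class
#'   among `clean`, `truncated`, `internal_priming`, `chimera`, `fusion`).
#' @export
simulate_tags <- function(cfg, ann) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  tr <- ann$truth
  genes <- ann$genes
  n <- nrow(genes)
  libs <- .lib_names(cfg$n_libraries)
  cw2 <- function(w) cbind(w[, 1L], w[, 1L] + w[, 2L])
  tss_cw <- cw2(tr$tss_w); pas_cw <- cw2(tr$pas_w)
  pick_idx <- function(g, cw) {
    u <- stats::runif(length(g))
    1L + (u > cw[g, 1L]) + (u > cw[g, 2L])
  }
  map_mrna <- function(g, off) {
    out <- integer(length(g))
    for (gi in unique(g)) {
      sel <- g == gi
      out[sel] <- .mrna_to_genomic(genes[gi, ], off[sel])
    }
    out
  }
  draw_mapq <- function(k) {
    q <- rep.int(60L, k)
    low <- stats::runif(k) < cfg$mapq_low_rate
    q[low] <- .runif_int(sum(low), c(0L, 30L))
    q
  }
  all_pairs <- vector("list", cfg$n_libraries)
  all_truth <- vector("list", cfg$n_libraries)
  for (l in seq_len(cfg$n_libraries)) {
    d <- cfg$depth
    g <- sample.int(n, d, replace = TRUE, prob = tr$expr_w[, l])
    ti <- pick_idx(g, tss_cw)
    pi_m <- pick_idx(g, pas_cw)
    pi <- pi_m
    coupled <- tr$preferred[g] & stats::runif(d) < cfg$coupling_share
    pi[coupled] <- tr$sigma[cbind(g[coupled], ti[coupled])]
    pos5 <- tr$tss_pos[cbind(g, ti)]
    pos3 <- tr$pas_pos[cbind(g, pi)]
    noise <- rep("clean", d)
    trunc <- stats::runif(d) < cfg$truncation_rate
    if (any(trunc)) {
      off <- as.integer(floor(stats::runif(sum(trunc)) *
                                tr$mrna_len[g[trunc]]))
      pos5[trunc] <- map_mrna(g[trunc], off)
      noise[trunc] <- "truncated"
    }
    iprime <- stats::runif(d) < cfg$internal_priming_rate &
      !is.na(tr$arun_pos[g])
    if (any(iprime)) {
      pos3[iprime] <- tr$arun_pos[g[iprime]] - 1L
      noise[iprime] <- "internal_priming"
    }
    chrom3 <- genes$chrom[g]; strand3 <- genes$strand[g]
    g3 <- g
    chim <- which(stats::runif(d) < cfg$chimera_rate)
    if (length(chim) > 1L) {
      perm <- sample(chim)
      pos3[chim] <- pos3[perm]
      chrom3[chim] <- chrom3[perm]
      strand3[chim] <- strand3[perm]
      g3[chim] <- g3[perm]
      noise[chim] <- "chimera"
    }
    lib_pairs <- data.frame(
      library_id = libs[l],
      chrom5 = genes$chrom[g], pos5 = pos5, strand5 = genes$strand[g],
      mapq5 = draw_mapq(d),
      chrom3 = chrom3, pos3 = pos3, strand3 = strand3,
      mapq3 = draw_mapq(d),
      end3_kind = "PAS", blocks3_sizes = ".", blocks3_starts = ".",
      stringsAsFactors = FALSE
    )
    lib_truth <- data.frame(gene5 = g, gene3 = g3, tss_idx = ti,
                            pas_idx = pi, noise = noise,
                            stringsAsFactors = FALSE)
    if (nrow(tr$fusions) > 0L) {
      for (f in seq_len(nrow(tr$fusions))) {
        nf <- max(1L, as.integer(round(tr$fusions$ppm[f] * 1e-6 * d)))
        g5 <- tr$fusions$gene5[f]; gf3 <- tr$fusions$gene3[f]
        lib_pairs <- rbind(lib_pairs, data.frame(
          library_id = libs[l],
          chrom5 = genes$chrom[g5], pos5 = tr$tss_pos[g5, 1L],
          strand5 = genes$strand[g5], mapq5 = 60L,
          chrom3 = genes$chrom[gf3], pos3 = tr$pas_pos[gf3, 1L],
          strand3 = genes$strand[gf3], mapq3 = 60L,
          end3_kind = "PAS", blocks3_sizes = ".", blocks3_starts = ".",
          stringsAsFactors = FALSE
        )[rep(1L, nf), ])
        lib_truth <- rbind(lib_truth, data.frame(
          gene5 = g5, gene3 = gf3, tss_idx = 1L, pas_idx = 1L,
          noise = "fusion", stringsAsFactors = FALSE)[rep(1L, nf), ])
      }
    }
    all_pairs[[l]] <- lib_pairs
    all_truth[[l]] <- lib_truth
  }
  if (cfg$emit_random) {
    span <- cfg$random_tag_span
    for (fr in names(cfg$random_fractions)) {
      b <- cfg$random_fractions[[fr]]
      d <- cfg$depth_random
      g <- sample.int(n, d, replace = TRUE, prob = tr$expr_w[, 1L])
      insert <- .runif_int(d, b)
      dd <- pmin(insert, tr$mrna_len[g])
      a <- pmax(0L, dd - span)
      pos5 <- tr$tss_pos[g, 1L]
      trunc <- stats::runif(d) < cfg$truncation_rate
      if (any(trunc)) {
        off <- as.integer(floor(stats::runif(sum(trunc)) *
                                  tr$mrna_len[g[trunc]]))
        pos5[trunc] <- map_mrna(g[trunc], off)
      }
      pos3 <- integer(d)
      sizes <- character(d)
      starts <- character(d)
      for (i in seq_len(d)) {
        blk <- .mrna_interval_to_blocks(genes[g[i], ], a[i], dd[i])
        left <- blk[1L, 1L]
        pos3[i] <- if (genes$strand[g[i]] == "+")
          blk[nrow(blk), 2L] - 1L else left
        sizes[i] <- paste(blk[, 2L] - blk[, 1L], collapse = ",")
        starts[i] <- paste(blk[, 1L] - left, collapse = ",")
      }
      all_pairs[[length(all_pairs) + 1L]] <- data.frame(
        library_id = fr,
        chrom5 = genes$chrom[g], pos5 = pos5, strand5 = genes$strand[g],
        mapq5 = draw_mapq(d),
        chrom3 = genes$chrom[g], pos3 = pos3, strand3 = genes$strand[g],
        mapq3 = draw_mapq(d),
        end3_kind = "RANDOM", blocks3_sizes = sizes,
        blocks3_starts = starts,
        stringsAsFactors = FALSE
      )
      all_truth[[length(all_truth) + 1L]] <- data.frame(
        gene5 = g, gene3 = g, tss_idx = 1L, pas_idx = NA_integer_,
        noise = ifelse(trunc, "truncated", "clean"),
        stringsAsFactors = FALSE
      )
    }
  }
  pairs <- do.call(rbind, all_pairs)
  truth_tags <- do.call(rbind, all_truth)
  pairs$pair_id <- seq_len(nrow(pairs))
  rownames(pairs) <- NULL
  rownames(truth_tags) <- NULL
  tot <- table(pairs$library_id)
  frac <- ifelse(names(tot) %in% names(cfg$random_fractions),
                 names(tot), "dT")
  stats <- data.frame(library_id = names(tot),
                      total_pairs = as.integer(tot),
                      fraction_label = frac,
                      stringsAsFactors = FALSE, row.names = NULL)
  list(pairs = pairs, stats = stats, truth_tags = truth_tags)
}

#' Exhaustive split-tag tiling of one gene's mRNA
#'
#' Deterministically generates RANDOM 3' tags that tile the mature mRNA of
#' one gene: one `span`-bp tag ends every `step` bases (plus one flush with
#' the 3' end), each carrying the exact split-block structure across
#' introns. Useful as the noiseless, exhaustively covered input under
#' which genome-guided assembly must reproduce the exon/intron structure
#' exactly.
#'
#' @param gene One row of a gene-model table.
#' @param span Tag span in mRNA bp (default 100).
#' @param step Spacing of tag 3' ends in mRNA bp (default `span %/% 2`).
#' @param library_id Library label for the emitted rows.
#' @return ENDPAIR v1 rows (`data.frame`), TSS tag at the annotated 5' end.
#' @export
tiling_random_tags <- function(gene, span = 100L, step = NULL,
                               library_id = "tiling") {
  step <- step %||% max(1L, span %/% 2L)
  L <- mrna_length(gene)
  ends <- unique(c(seq(min(span, L), L, by = step), L))
  rows <- lapply(ends, function(d) {
    blk <- .mrna_interval_to_blocks(gene, max(0L, d - span), d)
    left <- blk[1L, 1L]
    data.frame(
      library_id = library_id,
      chrom5 = gene$chrom, pos5 = gene_tss(gene), strand5 = gene$strand,
      mapq5 = 60L,
      chrom3 = gene$chrom,
      pos3 = if (gene$strand == "+") blk[nrow(blk), 2L] - 1L else left,
      strand3 = gene$strand, mapq3 = 60L,
      end3_kind = "RANDOM",
      blocks3_sizes = paste(blk[, 2L] - blk[, 1L], collapse = ","),
      blocks3_starts = paste(blk[, 1L] - left, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic data set
#'
#' Runs [simulate_annotation()] and [simulate_tags()].
#'
#' @param cfg A [sim_config()].
#' @return List with `cfg`, `genes`, `genome`, `cpg`, `truth`, `pairs`,
#'   `stats`, `truth_tags`.
#' @export
simulate_dataset <- function(cfg) {
  ann <- simulate_annotation(cfg)
  tags <- simulate_tags(cfg, ann)
  c(list(cfg = cfg), ann, tags)
}

#' Write a simulated data set to plain-text files
#'
#' Emits `genes.bed` (BED12), `pairs.tsv` (ENDPAIR v1), `libraries.tsv`,
#' `cpg.bed`, `truth_units.tsv` (per gene-site truth) and, when present,
#' `genome.fa`.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_models(sim$genes, file.path(dir, "genes.bed"))
  write_tag_pairs(sim$pairs, file.path(dir, "pairs.tsv"))
  utils::write.table(sim$stats, file.path(dir, "libraries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$cpg, file.path(dir, "cpg.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  tr <- sim$truth
  units <- do.call(rbind, lapply(seq_len(nrow(sim$genes)), function(i) {
    data.frame(
      gene_id = sim$genes$gene_id[i],
      site = c(paste0("TSS", seq_len(tr$n_tss[i])),
               paste0("PAS", seq_len(tr$n_pas[i]))),
      pos = c(tr$tss_pos[i, seq_len(tr$n_tss[i])],
              tr$pas_pos[i, seq_len(tr$n_pas[i])]),
      preferred_gene = tr$preferred[i],
      stringsAsFactors = FALSE
    )
  }))
  utils::write.table(units, file.path(dir, "truth_units.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(sim$genome)) {
    Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  }
  invisible(dir)
}
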