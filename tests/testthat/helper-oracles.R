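# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately avoid the code paths (and where possible the library
# calls) of the implementation they check.

# Poisson upper tail P(X >= k) by term-wise summation of the pmf, computed
# from the log-density recurrence (no ppois/dpois).
pois_tail_oracle <- function(k, lam) {
  if (k <= 0) return(1)
  term <- exp(-lam + k * log(lam) - lgamma(k + 1))
  if (term == 0) return(0)  # underflown far tail
  total <- term
  i <- k
  repeat {
    i <- i + 1
    term <- term * lam / i
    total <- total + term
    if (term <= total * 1e-16 && i > lam + k + 10) break
  }
  total
}

# Hypergeometric upper tail P(X >= k) by direct summation of choose() terms.
hyper_tail_oracle <- function(k, K, n, N) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Per-tag position category by exhaustive per-gene interval lookup, same
# precedence as the vectorised implementation.
classify_oracle <- function(chrom, pos, strand, genes, max_dist = 50000) {
  best <- 7L
  cats <- c("first_exon", "last_exon", "internal_exon", "intron",
            "upstream", "downstream", "intergenic")
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] != chrom || genes$strand[i] != strand) next
    ex_s <- genes$exon_starts[[i]]; ex_e <- genes$exon_ends[[i]]
    kx <- length(ex_s)
    plus <- genes$strand[i] == "+"
    f <- if (plus) 1L else kx
    l <- if (plus) kx else 1L
    r <- NULL
    if (pos >= ex_s[f] && pos < ex_e[f]) r <- 1L
    else if (pos >= ex_s[l] && pos < ex_e[l]) r <- 2L
    else if (kx > 2L && any(pos >= ex_s[2:(kx - 1)] &
                            pos < ex_e[2:(kx - 1)])) r <- 3L
    else if (pos >= genes$tx_start[i] && pos < genes$tx_end[i]) r <- 4L
    else {
      up <- if (plus) pos >= genes$tx_start[i] - max_dist &&
        pos < genes$tx_start[i]
      else pos >= genes$tx_end[i] && pos < genes$tx_end[i] + max_dist
      dn <- if (plus) pos >= genes$tx_end[i] &&
        pos < genes$tx_end[i] + max_dist
      else pos >= genes$tx_start[i] - max_dist && pos < genes$tx_start[i]
      if (up) r <- 5L else if (dn) r <- 6L
    }
    if (!is.null(r)) best <- min(best, r)
  }
  cats[best]
}

# Sense-strand window sequence by a route independent of .window_seq:
# reverse-complement the whole chromosome and read forward coordinates.
window_seq_oracle <- function(genome, chrom, pos, strand, from, to) {
  s <- genome[[chrom]]
  len <- length(s)
  if (strand == "-") {
    s <- Biostrings::reverseComplement(s)
    pos <- len - 1L - pos
  }
  g1 <- max(pos + from, 0L); g2 <- min(pos + to, len)
  if (g1 >= g2) return("")
  as.character(Biostrings::subseq(s, g1 + 1L, g2))
}
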