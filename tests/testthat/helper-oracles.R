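# Independent oracles used across the suite.

# Benjamini-Hochberg step-up, written directly from the procedure.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- pmin(rev(cummin(rev(ranked))), 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Degeneracy of one codon slot by explicit mutation + translation.
degeneracy_oracle <- function(codon, slot) {
  code <- Biostrings::GENETIC_CODE
  aa <- code[[codon]]
  alt <- setdiff(c("A", "C", "G", "T"), substr(codon, slot, slot))
  aas <- vapply(alt, function(b) {
    v <- codon
    substr(v, slot, slot) <- b
    code[[v]]
  }, character(1))
  if (all(aas == aa)) "four_fold"
  else if (all(aas != aa)) "zero_fold"
  else "other"
}

# Per-site heterozygosity as the exact fraction of mismatching read
# pairs, enumerated over all pairs drawn without replacement.
pair_pi_oracle <- function(counts_row) {
  m <- sum(counts_row)
  if (m < 2) return(NA_real_)
  mism <- 0
  for (a in 1:4) for (b in 1:4)
    if (a != b) mism <- mism + counts_row[a] * counts_row[b]
  mism / (m * (m - 1))
}

# Random count matrix with a mix of monomorphic and polymorphic sites.
random_counts <- function(n_sites, depth = 40, p_poly = 0.4) {
  m <- matrix(0L, n_sites, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_len(n_sites)) {
    d <- stats::rpois(1, depth) + 2L
    if (stats::runif(1) < p_poly) {
      ab <- sample.int(4, 2)
      k <- stats::rbinom(1, d, stats::runif(1, 0.1, 0.9))
      m[i, ab[1]] <- k
      m[i, ab[2]] <- d - k
    } else {
      m[i, sample.int(4, 1)] <- d
    }
  }
  m
}
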