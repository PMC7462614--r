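#' Per-site nucleotide diversity from pooled read counts
#'
#' Read-level heterozygosity with the small-sample correction
#' M/(M-1) * (1 - sum (c_a/M)^2), where M is the site depth and c_a the
#' read count of base a. Sites with fewer than two reads are undefined
#' (`NA`).
#'
#' @param counts sites x 4 integer matrix (A/C/G/T), or a length-4 vector.
#' @return numeric vector of per-site diversity values.
#' @export
site_pi <- function(counts) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  m <- rowSums(counts)
  pi <- ifelse(m >= 2,
               m / (m - 1) * (1 - rowSums((counts / pmax(m, 1))^2)),
               NA_real_)
  as.numeric(pi)
}

#' Harmonic number a_n = sum_{i=1}^{n-1} 1/i
#' @param n haploid sample size (>= 2).
#' @return Watterson's denominator.
#' @export
watterson_a <- function(n) {
  stopifnot(n >= 2)
  sum(1 / seq_len(n - 1))
}

#' Windowed pi and Watterson's theta for pooled counts
#'
#' Non-overlapping windows of `window_size` bp. A site is covered when its
#' depth lies within `[min_depth, max_depth]`; windows with a covered
#' fraction below `min_covered_fraction` are omitted. Within a window,
#' pi is the mean per-site diversity over covered sites and theta_W is
#' S / (a_n * covered sites) where S counts SNPs whose minor allele has at
#' least `min_count` reads and n is the haploid pool size.
#'
#' @param counts sites x 4 integer matrix (A/C/G/T).
#' @param pos 1-based site positions.
#' @param chrom chromosome name (scalar or per-site vector).
#' @param haploid_pool_size number of chromosomes in the pool.
#' @param window_size window length in bp (default 50 kb).
#' @param min_count minimum minor-allele read count for a SNP (default 2).
#' @param min_covered_fraction minimum covered fraction (default 0.3).
#' @param min_depth,max_depth coverage band for a site to count as
#'   covered.
#' @return data.table with `chrom`, `start`, `end` (1-based closed),
#'   `covered_fraction`, `n_snps`, `pi`, `theta_w`.
#' @export
window_stats <- function(counts, pos, chrom = "chr1", haploid_pool_size,
                         window_size = 50000, min_count = 2,
                         min_covered_fraction = 0.3,
                         min_depth = 1, max_depth = Inf) {
  if (haploid_pool_size < 2) stop("haploid_pool_size must be >= 2")
  if (length(pos) == 0) {
    return(data.table::data.table(
      chrom = character(), start = integer(), end = integer(),
      covered_fraction = numeric(), n_snps = integer(),
      pi = numeric(), theta_w = numeric()))
  }
  if (length(chrom) == 1) chrom <- rep(chrom, length(pos))
  a_n <- watterson_a(haploid_pool_size)
  depth <- rowSums(counts)
  covered <- depth >= min_depth & depth <= max_depth
  # alleles below the minimum count are masked (treated as sequencing
  # noise) before computing per-site diversity and SNP status
  masked <- counts
  masked[masked < min_count] <- 0L
  mdepth <- rowSums(masked)
  minor <- mdepth - apply(masked, 1, max)
  is_snp <- covered & minor >= min_count
  pis <- site_pi(masked)
  pis[!covered | is.na(pis)] <- 0

  dt <- data.table::data.table(
    chrom = chrom,
    win = (pos - 1L) %/% as.integer(window_size),
    covered = covered, snp = is_snp, pi_site = pis)
  agg <- dt[, .(n_cov = sum(covered), n_snps = sum(snp),
                pi_sum = sum(pi_site)), by = .(chrom, win)]
  agg[, covered_fraction := n_cov / window_size]
  agg <- agg[covered_fraction >= min_covered_fraction & n_cov > 0]
  agg[, `:=`(start = win * as.integer(window_size) + 1L,
             end = (win + 1L) * as.integer(window_size),
             pi = pi_sum / n_cov,
             theta_w = n_snps / (a_n * n_cov))]
  data.table::setorder(agg, chrom, start)
  agg[, .(chrom, start, end, covered_fraction, n_snps, pi, theta_w)]
}

#' Effective population size from the population mutation rate
#'
#' Watterson's theta is the compound parameter theta = 2 p N_e mu with p
#' the ploidy, so N_e = theta / (2 p mu).
#'
#' @param theta per-site population mutation rate estimate.
#' @param mu mutation rate per bp per generation (default 2.6321e-9).
#' @param ploidy organism ploidy (default 2).
#' @return list with `theta`, `mu`, `ploidy` and `ne`.
#' @export
estimate_ne <- function(theta, mu = 2.6321e-9, ploidy = 2) {
  if (mu <= 0) stop("mu must be > 0")
  if (theta < 0) stop("theta must be >= 0")
  list(theta = theta, mu = mu, ploidy = ploidy,
       ne = theta / (2 * ploidy * mu))
}
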