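#' Classical pi-based F_ST from pooled counts
#'
#' F_ST = (pi_total - pi_within) / pi_total with pi_within the average of
#' the two within-pool diversities and pi_total the diversity of the
#' pooled counts. Negative values are clamped to 0; sites (or windows)
#' with pi_total = 0 are undefined (`NA`).
#'
#' @param counts1,counts2 sites x 4 integer matrices (A/C/G/T), or
#'   length-4 vectors for a single site.
#' @return numeric vector of per-site F_ST values.
#' @export
fst_from_counts <- function(counts1, counts2) {
  if (is.null(dim(counts1))) counts1 <- matrix(counts1, nrow = 1)
  if (is.null(dim(counts2))) counts2 <- matrix(counts2, nrow = 1)
  if (any(rowSums(counts1) == 0) || any(rowSums(counts2) == 0))
    stop("zero depth in one of the pools")
  pi1 <- site_pi(counts1)
  pi2 <- site_pi(counts2)
  pit <- site_pi(counts1 + counts2)
  piw <- (pi1 + pi2) / 2
  fst <- ifelse(pit > 0, (pit - piw) / pit, NA_real_)
  pmax(fst, 0)
}

#' Windowed pairwise F_ST
#'
#' Aggregates per-site diversities over SNPs in non-overlapping windows:
#' F_ST(window) = (sum pi_total - sum pi_within) / sum pi_total over the
#' SNP sites of the window. A site enters as a SNP when both pools meet
#' the coverage band and the combined minor-allele count is at least
#' `min_count`.
#'
#' @param counts1,counts2 sites x 4 count matrices of the two pools.
#' @param pos 1-based positions.
#' @param chrom chromosome name (scalar or vector).
#' @param window_size window length (default 50 kb); use a window larger
#'   than the region (or [gene_fst()]) for a single-span estimate.
#' @param min_count combined minor-allele count for a SNP (default 4).
#' @param min_depth minimum depth in each pool (default 20).
#' @param max_depth1,max_depth2 per-pool maximum depths.
#' @param min_covered_fraction minimum fraction of window positions that
#'   are covered in both pools (default 0.3; set 0 to disable).
#' @return data.table with `chrom`, `start`, `end`, `n_snps`, `fst`.
#' @export
window_fst <- function(counts1, counts2, pos, chrom = "chr1",
                       window_size = 50000, min_count = 4,
                       min_depth = 20, max_depth1 = Inf, max_depth2 = Inf,
                       min_covered_fraction = 0.3) {
  if (length(chrom) == 1) chrom <- rep(chrom, length(pos))
  d1 <- rowSums(counts1)
  d2 <- rowSums(counts2)
  covered <- d1 >= min_depth & d1 <= max_depth1 &
    d2 >= min_depth & d2 <= max_depth2
  comb <- counts1 + counts2
  # alleles below the minimum combined count are masked as noise
  allowed <- comb >= min_count
  m1 <- counts1 * allowed
  m2 <- counts2 * allowed
  mc <- comb * allowed
  minor <- rowSums(mc) - apply(mc, 1, max)
  snp <- covered & minor >= min_count

  pi1 <- site_pi(m1)
  pi2 <- site_pi(m2)
  pit <- site_pi(mc)
  pi1[is.na(pi1)] <- 0
  pi2[is.na(pi2)] <- 0
  pit[is.na(pit)] <- 0
  piw <- (pi1 + pi2) / 2

  dt <- data.table::data.table(
    chrom = chrom, win = (pos - 1L) %/% as.integer(window_size),
    covered = covered, snp = snp,
    pit = ifelse(snp, pit, 0), piw = ifelse(snp, piw, 0))
  agg <- dt[, .(n_cov = sum(covered), n_snps = sum(snp),
                pit = sum(pit), piw = sum(piw)), by = .(chrom, win)]
  agg[, covered_fraction := n_cov / window_size]
  agg <- agg[covered_fraction >= min_covered_fraction]
  agg[, fst := ifelse(pit > 0, pmax((pit - piw) / pit, 0), NA_real_)]
  agg[, `:=`(start = win * as.integer(window_size) + 1L,
             end = (win + 1L) * as.integer(window_size))]
  data.table::setorder(agg, chrom, start)
  agg[, .(chrom, start, end, covered_fraction, n_snps, fst)]
}

#' Per-gene F_ST
#'
#' Single-span F_ST over each gene's extent (the "one window per gene"
#' device), using the same site filters as [window_fst()].
#'
#' @param counts1,counts2 count matrices over all sites.
#' @param pos 1-based positions.
#' @param genes data.table with `gene_id`, `start`, `end` (1-based
#'   closed).
#' @inheritParams window_fst
#' @return data.table with `gene_id`, `n_snps`, `fst`.
#' @export
gene_fst <- function(counts1, counts2, pos, genes, min_count = 4,
                     min_depth = 20, max_depth1 = Inf, max_depth2 = Inf) {
  res <- lapply(seq_len(nrow(genes)), function(k) {
    sel <- pos >= genes$start[k] & pos <= genes$end[k]
    if (!any(sel))
      return(data.table::data.table(gene_id = genes$gene_id[k],
                                    n_snps = 0L, fst = NA_real_))
    w <- window_fst(counts1[sel, , drop = FALSE], counts2[sel, , drop = FALSE],
                    pos[sel], chrom = "g",
                    window_size = max(genes$end[k], 1) + 1L,
                    min_count = min_count, min_depth = min_depth,
                    max_depth1 = max_depth1, max_depth2 = max_depth2,
                    min_covered_fraction = 0)
    data.table::data.table(gene_id = genes$gene_id[k],
                           n_snps = if (nrow(w)) w$n_snps else 0L,
                           fst = if (nrow(w)) w$fst else NA_real_)
  })
  data.table::rbindlist(res)
}

#' Z-transformed F_ST outlier scan
#'
#' Z-transforms the window F_ST values of one pairwise comparison and
#' flags windows beyond empirical quantile thresholds (type-7 quantiles;
#' default the 0.5% tails).
#'
#' @param fst vector of window F_ST values (NAs dropped).
#' @param lower_q,upper_q tail quantiles (defaults 0.005 and 0.995).
#' @return data.table with `fst`, `z_fst`, `outlier` in
#'   `{"low", "none", "high"}`, in input order (NA rows removed).
#' @export
zfst_outliers <- function(fst, lower_q = 0.005, upper_q = 0.995) {
  fst <- fst[!is.na(fst)]
  if (length(fst) < 200)
    warning("fewer than 200 windows; outlier quantiles are unstable")
  s <- stats::sd(fst)
  if (!is.finite(s) || s == 0) stop("zero variance across windows")
  z <- (fst - mean(fst)) / s
  lo <- stats::quantile(z, lower_q, type = 7, names = FALSE)
  hi <- stats::quantile(z, upper_q, type = 7, names = FALSE)
  data.table::data.table(
    fst = fst, z_fst = z,
    outlier = ifelse(z > hi, "high", ifelse(z < lo, "low", "none")))
}

#' Fisher's exact test per SNP with Benjamini-Hochberg correction
#'
#' Two-sided Fisher's exact test on the 2 x 2 table of major/minor allele
#' counts (alleles defined on the combined pools) between the two pools,
#' with BH adjustment across all tested SNPs. Tables with a zero margin
#' give p = 1.
#'
#' @param counts1,counts2 sites x 4 count matrices.
#' @param alpha significance level on the adjusted p-values (default
#'   0.001).
#' @return data.table with `p`, `q` (BH-adjusted) and `significant`.
#' @export
snp_fisher_bh <- function(counts1, counts2, alpha = 0.001) {
  if (is.null(dim(counts1))) counts1 <- matrix(counts1, nrow = 1)
  if (is.null(dim(counts2))) counts2 <- matrix(counts2, nrow = 1)
  comb <- counts1 + counts2
  n <- nrow(comb)
  ord1 <- max.col(comb, ties.method = "first")
  tmp <- comb
  tmp[cbind(seq_len(n), ord1)] <- -1L
  ord2 <- max.col(tmp, ties.method = "last")
  p <- vapply(seq_len(n), function(i) {
    tab <- rbind(c(counts1[i, ord1[i]], counts1[i, ord2[i]]),
                 c(counts2[i, ord1[i]], counts2[i, ord2[i]]))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  data.table::data.table(p = p, q = q, significant = q < alpha)
}

#' Candidate genes under the three-criteria outlier rule
#'
#' A gene is a selection candidate when (1) it lies in a 50 kb window
#' whose Z_FST exceeds the upper outlier threshold, (2) its gene-wise
#' F_ST exceeds the corresponding upper quantile of gene F_ST values, and
#' (3) it contains at least one SNP significant under the BH-corrected
#' Fisher's exact test.
#'
#' @param genes data.table with `gene_id`, `start`, `end`.
#' @param windows window table with `start`, `end` and `outlier` (from
#'   [window_fst()] joined with [zfst_outliers()]).
#' @param gene_fst_tab output of [gene_fst()].
#' @param snp_pos positions of tested SNPs.
#' @param snp_sig logical significance per SNP (from [snp_fisher_bh()]).
#' @param upper_q gene-F_ST quantile (default 0.995).
#' @return data.table with the three criteria as logical columns and
#'   `candidate`.
#' @export
candidate_genes <- function(genes, windows, gene_fst_tab, snp_pos, snp_sig,
                            upper_q = 0.995) {
  thr <- stats::quantile(gene_fst_tab$fst, upper_q, na.rm = TRUE, type = 7,
                         names = FALSE)
  high_w <- windows[windows$outlier == "high", , drop = FALSE]
  res <- data.table::as.data.table(genes)[, .(gene_id, start, end)]
  res[, in_outlier_window := vapply(seq_len(.N), function(k)
    any(high_w$start <= end[k] & high_w$end >= start[k]), logical(1))]
  res <- merge(res, gene_fst_tab[, .(gene_id, fst)], by = "gene_id",
               all.x = TRUE, sort = FALSE)
  res[, gene_fst_high := !is.na(fst) & fst > thr]
  res[, has_sig_snp := vapply(seq_len(.N), function(k)
    any(snp_sig[snp_pos >= start[k] & snp_pos <= end[k]]), logical(1))]
  res[, candidate := in_outlier_window & gene_fst_high & has_sig_snp]
  res
}

#' Neighbor-joining tree from a pairwise F_ST matrix
#'
#' Standard neighbor joining on the genome-wide pairwise distance matrix;
#' the tree is unrooted and branch lengths may be negative (reported
#' as-is).
#'
#' @param d symmetric distance matrix with zero diagonal, >= 3 taxa.
#' @param labels optional taxon labels (default from `d` dimnames).
#' @return newick string (with trailing newline stripped).
#' @export
nj_tree <- function(d, labels = NULL) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have zero diagonal")
  if (!is.null(labels)) dimnames(d) <- list(labels, labels)
  if (is.null(rownames(d)))
    dimnames(d) <- list(paste0("t", seq_len(nrow(d))),
                        paste0("t", seq_len(nrow(d))))
  tr <- ape::nj(stats::as.dist(d))
  ape::write.tree(tr)
}
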