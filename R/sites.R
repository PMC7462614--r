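#' Degeneracy lookup table for the standard genetic code
#'
#' For each codon and codon slot (1-3): `four_fold` when all four bases at
#' that slot encode the same amino acid, `zero_fold` when every change
#' alters the amino acid, otherwise `other`.
#'
#' @return 64 x 3 character matrix, rows named by codon.
#' @keywords internal
degeneracy_table <- function() {
  cache <- get0(".degeneracy_cache", envir = .poolpopgen_env)
  if (!is.null(cache)) return(cache)
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  codons <- names(code)
  out <- matrix("other", nrow = 64, ncol = 3, dimnames = list(codons, NULL))
  for (cd in codons) {
    aa <- code[[cd]]
    for (slot in 1:3) {
      variants <- vapply(bases, function(b) {
        v <- cd
        substr(v, slot, slot) <- b
        code[[v]]
      }, character(1))
      n_same <- sum(variants == aa)  # includes the codon itself
      out[cd, slot] <- if (n_same == 4) "four_fold"
        else if (n_same == 1) "zero_fold" else "other"
    }
  }
  assign(".degeneracy_cache", out, envir = .poolpopgen_env)
  out
}

.poolpopgen_env <- new.env(parent = emptyenv())

.revcomp <- function(x) {
  vapply(x, function(s) {
    paste0(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Classify coding-site degeneracy
#'
#' Walks every CDS of the annotation along the reference and assigns each
#' coding position a degeneracy class under the standard genetic code:
#' `four_fold` (all substitutions synonymous), `zero_fold` (all
#' substitutions non-synonymous) or `other` (2- and 3-fold sites).
#' Reverse-strand CDS are handled by reverse complementation. Codons
#' containing ambiguous bases are excluded; internal stop codons trigger
#' a warning and are excluded.
#'
#' @param sequences named character vector of chromosome sequences (as
#'   from [read_fasta()]).
#' @param cds CDS table (as from [read_cds_gtf()]): `chrom`, 1-based
#'   closed `start`/`end`, `strand`, `gene_id`. Multi-interval genes are
#'   concatenated in genomic order (reversed on the minus strand).
#' @return data.table with `chrom`, `pos` (0-based), `gene_id`, `strand`,
#'   `codon_index` (1-based), `codon_slot` (1-3) and `class`.
#' @export
classify_degeneracy <- function(sequences, cds) {
  tab <- degeneracy_table()
  cds <- data.table::as.data.table(cds)
  out <- vector("list", length(unique(cds$gene_id)))
  i <- 0L
  for (gid in unique(cds$gene_id)) {
    g <- cds[gene_id == gid]
    data.table::setorder(g, start)
    chromseq <- sequences[[g$chrom[1]]]
    if (is.null(chromseq)) stop("chromosome not in reference: ", g$chrom[1])
    gpos <- unlist(lapply(seq_len(nrow(g)),
                          function(k) g$start[k]:g$end[k]))  # 1-based
    seq_fwd <- substring(chromseq, gpos, gpos)
    minus <- g$strand[1] == "-"
    if (minus) {
      gpos <- rev(gpos)
      codseq <- chartr("ACGT", "TGCA", rev(seq_fwd))
    } else codseq <- seq_fwd
    n_codon <- length(codseq) %/% 3L
    if (n_codon == 0) next
    use <- seq_len(3L * n_codon)
    codseq <- codseq[use]
    gpos <- gpos[use]
    codon_index <- rep(seq_len(n_codon), each = 3L)
    codons <- paste0(codseq[c(TRUE, FALSE, FALSE)],
                     codseq[c(FALSE, TRUE, FALSE)],
                     codseq[c(FALSE, FALSE, TRUE)])
    bad <- !codons %in% rownames(tab)
    stop_cd <- !bad & Biostrings::GENETIC_CODE[codons] == "*"
    if (any(stop_cd[-length(stop_cd)]))
      warning("internal stop codon(s) in gene ", gid, "; codon(s) excluded")
    keep_codon <- !(bad | stop_cd)
    if (!any(keep_codon)) next
    cls <- matrix("other", nrow = n_codon, ncol = 3)
    cls[keep_codon, ] <- tab[codons[keep_codon], , drop = FALSE]
    keep_site <- rep(keep_codon, each = 3L)
    slot <- rep(1:3, times = n_codon)
    i <- i + 1L
    out[[i]] <- data.table::data.table(
      chrom = g$chrom[1],
      pos = gpos[keep_site] - 1L,
      gene_id = gid,
      strand = g$strand[1],
      codon_index = codon_index[keep_site],
      codon_slot = slot[keep_site],
      class = as.vector(t(cls))[keep_site])
  }
  res <- data.table::rbindlist(out[seq_len(i)])
  data.table::setorder(res, chrom, pos)
  res
}

#' Majority-rule allele call from read counts
#'
#' The allele with more supporting reads wins; uncovered sites and sites
#' with more than two observed alleles are masked as `N`, as are exact
#' ties (conservative masking).
#'
#' @param counts integer matrix (sites x 4, columns A/C/G/T) or a length-4
#'   vector for a single site.
#' @return character vector of called bases (`"N"` where masked).
#' @export
call_major_allele <- function(counts) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  bases <- c("A", "C", "G", "T")
  n_obs <- rowSums(counts > 0)
  top <- max.col(counts, ties.method = "first")
  topcount <- counts[cbind(seq_len(nrow(counts)), top)]
  # tie: another allele reaches the top count
  tie <- rowSums(counts == topcount) > 1L & topcount > 0L
  out <- bases[top]
  out[n_obs == 0 | n_obs > 2 | tie] <- "N"
  out
}

#' Polarize pooled counts against an outgroup base
#'
#' Determines, per site, the derived allele (the allele not carried by
#' the outgroup), its frequency (DAF), and a status:
#' \itemize{
#'   \item `excluded`: coverage outside `[min_depth, max_depth]`, outgroup
#'     base not A/C/G/T, three or more alleles with >= 2 reads, or a
#'     biallelic site whose two alleles both differ from the outgroup.
#'   \item `monomorphic`: a single effective allele (any minor allele has
#'     at most one supporting read) equal to the outgroup base, or a DAF
#'     below `daf_min` (the derived allele is effectively absent).
#'   \item `fixed`: a single effective allele differing from the outgroup
#'     (a divergent site), or a DAF above `daf_max`.
#'   \item `polymorphic`: DAF in `[daf_min, daf_max]`.
#' }
#' DAF is computed from the raw counts of the two most-supported alleles.
#'
#' @param counts sites x 4 integer matrix (A/C/G/T).
#' @param outgroup_base character vector of outgroup bases per site.
#' @param min_depth,max_depth coverage bounds (inclusive).
#' @param daf_min,daf_max polymorphic DAF band (defaults 0.05 and 0.95).
#' @return data.table with `outgroup`, `derived`, `derived_count`,
#'   `total_count`, `daf`, `status`.
#' @export
polarize <- function(counts, outgroup_base, min_depth = 1, max_depth = Inf,
                     daf_min = 0.05, daf_max = 0.95) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  bases <- c("A", "C", "G", "T")
  n <- nrow(counts)
  cov <- rowSums(counts)
  og <- toupper(outgroup_base)
  ogi <- match(og, bases)

  ord1 <- max.col(counts, ties.method = "first")
  c1 <- counts[cbind(seq_len(n), ord1)]
  tmp <- counts
  tmp[cbind(seq_len(n), ord1)] <- -1L
  ord2 <- max.col(tmp, ties.method = "last")
  c2 <- counts[cbind(seq_len(n), ord2)]
  c2[c2 < 0L] <- 0L
  n_eff <- rowSums(counts >= 2L)  # alleles with real support

  excluded <- is.na(ogi) | cov < min_depth | cov > max_depth | n_eff > 2L
  major_is_og <- ord1 == ogi
  minor_is_og <- ord2 == ogi & c2 > 0L

  derived_i <- ifelse(major_is_og, ord2, ord1)
  derived_count <- ifelse(major_is_og, c2, c1)
  total <- c1 + c2
  # biallelic with outgroup matching neither allele: cross-species triallelic
  biallelic <- c2 >= 1L
  excluded <- excluded | (biallelic & !major_is_og & !minor_is_og & !is.na(ogi))

  daf <- ifelse(total > 0, derived_count / total, NA_real_)
  mono <- c2 <= 1L  # single-read minor alleles treated as absent
  status <- rep("polymorphic", n)
  status[mono & major_is_og] <- "monomorphic"
  status[mono & !major_is_og] <- "fixed"
  status[!mono & daf < daf_min] <- "monomorphic"
  status[!mono & daf > daf_max] <- "fixed"
  status[excluded] <- "excluded"

  derived <- bases[derived_i]
  derived[derived_count == 0L] <- NA_character_
  data.table::data.table(
    outgroup = og,
    derived = derived,
    derived_count = derived_count,
    total_count = cov,
    daf = daf,
    status = status)
}

#' Posterior segregation filter for polymorphic sites
#'
#' A Bayesian stand-in for an external pooled SNP caller: each site is
#' modelled as either monomorphic for one of its two alleles (minor reads
#' arise from sequencing error at rate `error_rate`) or truly segregating
#' with a uniform prior on the allele frequency, with equal prior weight
#' on the three states. A polymorphic site is retained when the posterior
#' probability of segregation exceeds `threshold`.
#'
#' @param minor_count,depth per-site minor allele read count and total
#'   depth.
#' @param threshold posterior probability cutoff in (0, 1).
#' @param error_rate assumed per-base error rate.
#' @return logical vector: keep the site as polymorphic.
#' @export
segregation_filter <- function(minor_count, depth, threshold = 0.9,
                               error_rate = 0.01) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly between 0 and 1")
  lik_mono1 <- stats::dbinom(minor_count, depth, error_rate)
  lik_mono2 <- stats::dbinom(minor_count, depth, 1 - error_rate)
  lik_seg <- 1 / (depth + 1)  # integral of the binomial over uniform f
  post <- lik_seg / (lik_seg + lik_mono1 + lik_mono2)
  post > threshold
}

#' Posterior probability of segregation
#'
#' The posterior used by [segregation_filter()], exposed for inspection.
#' @inheritParams segregation_filter
#' @return numeric vector of posterior probabilities.
#' @export
segregation_posterior <- function(minor_count, depth, error_rate = 0.01) {
  lik_mono1 <- stats::dbinom(minor_count, depth, error_rate)
  lik_mono2 <- stats::dbinom(minor_count, depth, 1 - error_rate)
  lik_seg <- 1 / (depth + 1)
  lik_seg / (lik_seg + lik_mono1 + lik_mono2)
}
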