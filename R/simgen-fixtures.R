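#' Codon-structured random reference sequence for a layout
#'
#' Builds a reference genome whose coding sequences are random codons from
#' the six four-fold-degenerate codon families GCN (Ala), GGN (Gly), GTN
#' (Val), ACN (Thr), CCN (Pro) and TCN (Ser). For every codon in these
#' families the third position is exactly four-fold degenerate and the
#' first two positions are zero-fold degenerate, so the degeneracy classes
#' of the emitted genome coincide with the simulator's neutral/selected
#' site pattern and contain no stop codons. Spacer sequence is uniform
#' random.
#'
#' @param layout a [genome_layout()].
#' @return a character string of length [genome_length()].
#' @export
codon_reference <- function(layout) {
  families <- c("GC", "GG", "GT", "AC", "CC", "TC")
  bases <- c("A", "C", "G", "T")
  n_codons <- layout$cds_length %/% 3L
  build_cds <- function() {
    fam <- sample(families, n_codons, replace = TRUE)
    third <- sample(bases, n_codons, replace = TRUE)
    paste0(paste0(fam, third), collapse = "")
  }
  pieces <- character(2L * layout$n_cds)
  for (i in seq_len(layout$n_cds)) {
    pieces[2L * i - 1L] <- build_cds()
    pieces[2L * i] <- paste0(sample(bases, layout$spacer_length,
                                    replace = TRUE), collapse = "")
  }
  paste0(pieces, collapse = "")
}

#' CDS annotation implied by a layout
#'
#' @param layout a [genome_layout()].
#' @param chrom chromosome name.
#' @return data.table with 1-based closed `start`/`end`, `strand`,
#'   `gene_id` -- one single-exon CDS per gene, all on the plus strand.
#' @export
layout_cds_table <- function(layout, chrom = "chr1") {
  unit <- layout$cds_length + layout$spacer_length
  start <- (seq_len(layout$n_cds) - 1L) * unit + 1L
  data.table::data.table(
    chrom = chrom,
    start = start,
    end = start + layout$cds_length - 1L,
    strand = "+",
    gene_id = sprintf("g%05d", seq_len(layout$n_cds)))
}

#' Diverge an outgroup sequence from a reference
#'
#' Jukes-Cantor-style divergence: each site is substituted independently
#' with probability `divergence`, to a uniformly chosen different base.
#' The substituted positions are returned so tests can use them as an
#' oracle.
#'
#' @param reference character string (A/C/G/T).
#' @param divergence per-site substitution probability in \[0, 0.75);
#'   either a scalar or a per-site vector (allowing, e.g., reduced
#'   divergence at selected sites to emulate purifying selection on the
#'   outgroup lineage).
#' @return list with `sequence` (character string) and `positions`
#'   (0-based substituted positions).
#' @export
mutate_outgroup <- function(reference, divergence) {
  if (nchar(reference) == 0) stop("empty reference")
  if (any(divergence < 0) || any(divergence >= 0.75))
    stop("divergence must lie in [0, 0.75)")
  ref <- strsplit(reference, "")[[1]]
  if (length(divergence) > 1 && length(divergence) != length(ref))
    stop("per-site divergence must match the reference length")
  hit <- which(stats::runif(length(ref)) < divergence)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    # draw a uniformly different base per substituted site
    shift <- sample.int(3L, length(hit), replace = TRUE)
    cur <- match(ref[hit], bases)
    ref[hit] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  }
  list(sequence = paste0(ref, collapse = ""), positions = hit - 1L)
}

#' Pooled sequencing of a set of sampled chromosomes
#'
#' Emulates pool-seq read counts: per site, total depth is
#' Poisson(`depth`), and each read reports the truth with probability
#' 1 - `error_rate`, otherwise one of the three other bases uniformly.
#'
#' @param freq derived allele frequency per site (vector over sites).
#' @param ref_base,derived_base base characters per site.
#' @param depth mean coverage.
#' @param error_rate per-base error probability in \[0, 0.25).
#' @return integer matrix (sites x 4) of A/C/G/T read counts.
#' @export
pool_reads <- function(freq, ref_base, derived_base, depth, error_rate = 0) {
  n <- length(freq)
  if (n == 0) stop("empty sample")
  if (depth <= 0) stop("depth must be > 0")
  if (error_rate < 0 || error_rate >= 0.25)
    stop("error_rate must lie in [0, 0.25)")
  bases <- c("A", "C", "G", "T")
  ri <- match(ref_base, bases)
  di <- match(derived_base, bases)
  di[is.na(di)] <- ri[is.na(di)]
  # per-base emission probability: truth mixture perturbed by error
  p <- matrix(error_rate / 3, nrow = n, ncol = 4)
  truth_ref <- (1 - freq) * (1 - error_rate) + freq * error_rate / 3
  truth_der <- freq * (1 - error_rate) + (1 - freq) * error_rate / 3
  p[cbind(seq_len(n), ri)] <- truth_ref
  p[cbind(seq_len(n), di)] <- p[cbind(seq_len(n), di)] +
    truth_der - error_rate / 3
  same <- which(ri == di)
  if (length(same))  # monomorphic at the reference base
    p[cbind(same, ri[same])] <- 1 - error_rate
  p <- p / rowSums(p)

  d <- stats::rpois(n, depth)
  counts <- matrix(0L, nrow = n, ncol = 4,
                   dimnames = list(NULL, bases))
  remaining <- d
  acc <- rep(0, n)
  for (b in 1:3) {
    pb <- p[, b] / pmax(1 - acc, 1e-12)
    pb <- pmin(pmax(pb, 0), 1)
    counts[, b] <- stats::rbinom(n, remaining, pb)
    remaining <- remaining - counts[, b]
    acc <- acc + p[, b]
  }
  counts[, 4] <- remaining
  counts
}

#' Write a complete synthetic study system to disk
#'
#' Emits everything the analysis pipeline consumes, with known truth: the
#' reference FASTA, a CDS annotation GTF (1-based closed, `gene_id`
#' attributes), an outgroup pseudogenome FASTA diverged from the
#' reference, a PoPoolation2-style sync file of pooled read counts per
#' population, and per-population truth tables of mutation positions,
#' selection coefficients, classes and sample frequencies.
#'
#' @param sim a [simulate_forward()] result.
#' @param dir output directory (created if needed).
#' @param depth mean pool coverage per population (recycled).
#' @param error_rate per-base sequencing error.
#' @param divergence outgroup per-site substitution rate at neutral and
#'   non-coding positions.
#' @param nonsyn_divergence_ratio multiplier on `divergence` at
#'   selected-class (non-synonymous-like) positions, emulating purifying
#'   selection on the outgroup lineage (default 0.25).
#' @param chrom chromosome name used in all outputs.
#' @param pop_names population names (default `names(sim$populations)`).
#' @return invisibly, a named list of the written file paths.
#' @export
write_sim_fixtures <- function(sim, dir, depth = 50, error_rate = 0,
                               divergence = 0.02,
                               nonsyn_divergence_ratio = 0.25,
                               chrom = "chr1",
                               pop_names = names(sim$populations)) {
  stopifnot(inherits(sim, "sim_output"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layout <- sim$config$layout
  L <- genome_length(layout)
  depth <- rep(depth, length.out = length(sim$populations))

  reference <- codon_reference(layout)
  ref_vec <- strsplit(reference, "")[[1]]
  div_site <- rep(divergence, L)
  div_site[layout_site_classes(layout) == 2L] <-
    divergence * nonsyn_divergence_ratio
  og <- mutate_outgroup(reference, div_site)

  bases <- c("A", "C", "G", "T")
  # derived base per mutation: uniform among the three non-reference bases
  muts <- sim$mutations
  shift <- sample.int(3L, nrow(muts), replace = TRUE)
  cur <- match(ref_vec[muts$pos + 1L], bases)
  derived <- bases[((cur - 1L + shift) %% 4L) + 1L]

  paths <- list(
    reference = file.path(dir, "reference.fa"),
    outgroup = file.path(dir, "outgroup.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    sync = file.path(dir, "counts.sync"))

  write_fasta(stats::setNames(reference, chrom), paths$reference)
  write_fasta(stats::setNames(og$sequence, chrom), paths$outgroup)
  write_cds_gtf(layout_cds_table(layout, chrom), paths$gtf)

  count_cols <- vector("list", length(sim$populations))
  for (p in seq_along(sim$populations)) {
    freqs <- sample_site_frequencies(sim, p)
    fvec <- rep(0, L)
    dvec <- ref_vec
    fvec[freqs$pos + 1L] <- freqs$freq
    dvec[freqs$pos + 1L] <- derived[freqs$id]
    cm <- pool_reads(fvec, ref_vec, dvec, depth[p], error_rate)
    count_cols[[p]] <- paste(cm[, 1], cm[, 2], cm[, 3], cm[, 4], 0L, 0L,
                             sep = ":")
    truth <- data.table::copy(freqs)
    truth[, derived_base := derived[id]]
    tp <- file.path(dir, sprintf("truth_%s.tsv", pop_names[p]))
    data.table::fwrite(truth, tp, sep = "\t")
    paths[[paste0("truth_", pop_names[p])]] <- tp
  }

  sync <- data.table::data.table(chrom = chrom, pos = seq_len(L),
                                 ref = ref_vec)
  for (p in seq_along(count_cols))
    sync[, (pop_names[p]) := count_cols[[p]]]
  data.table::fwrite(sync, paths$sync, sep = "\t", col.names = FALSE)

  invisible(paths)
}

#' McDonald-Kreitman tables directly from simulation truth
#'
#' Bypasses pooled sequencing: derived allele frequencies are taken from
#' the sampled diploids and the outgroup is assumed to carry the
#' ancestral (reference) state everywhere. Neutral-class mutations play
#' the role of synonymous sites, selected-class mutations the role of
#' non-synonymous sites; genes are the CDS blocks of the layout.
#'
#' @param sim a [simulate_forward()] result.
#' @param pop population name or index.
#' @param daf_fixed frequency above which a segregating mutation is
#'   promoted to a fixed difference (default 0.95).
#' @param daf_min polymorphic lower bound (default 0.05).
#' @param outgroup_divergence per-site substitution rate on the outgroup
#'   lineage at synonymous-like positions; adds Poisson-distributed fixed
#'   differences per gene on top of the population's own fixations
#'   (default 0: the outgroup is the common ancestor itself).
#' @param nonsyn_divergence_ratio multiplier on `outgroup_divergence` at
#'   selected positions (purifying selection on the outgroup lineage).
#' @param outgroup_D optional pre-drawn per-gene outgroup divergence from
#'   [draw_outgroup_mk_divergence()]; because all daughter populations
#'   share one outgroup branch, comparisons across populations of the
#'   same replicate should pass the same draw.
#' @return per-gene MK table (`gene_id`, `Dn`, `Ds`, `Pn`, `Ps`) as
#'   produced by [mk_counts()].
#' @export
sim_mk_tables <- function(sim, pop, daf_fixed = 0.95, daf_min = 0.05,
                          outgroup_divergence = 0,
                          nonsyn_divergence_ratio = 0.25,
                          outgroup_D = NULL) {
  layout <- sim$config$layout
  freqs <- sample_site_frequencies(sim, pop)
  unit <- layout$cds_length + layout$spacer_length
  freqs[, gene_id := sprintf("g%05d", pos %/% unit + 1L)]
  freqs[, within := pos %% unit]
  freqs <- freqs[within < layout$cds_length]
  freqs[, degeneracy := ifelse(class == "neutral", "four_fold", "zero_fold")]
  freqs[, status := ifelse(freq > daf_fixed, "fixed",
                    ifelse(freq < daf_min, "monomorphic", "polymorphic"))]
  pol <- freqs[, .(gene_id, degeneracy, daf = freq, status)]
  all_genes <- sprintf("g%05d", seq_len(layout$n_cds))
  mk <- mk_counts(pol, genes = all_genes)
  if (is.null(outgroup_D) && outgroup_divergence > 0)
    outgroup_D <- draw_outgroup_mk_divergence(layout, outgroup_divergence,
                                              nonsyn_divergence_ratio)
  if (!is.null(outgroup_D)) {
    stopifnot(identical(outgroup_D$gene_id, mk$genes$gene_id))
    mk$genes$Ds <- mk$genes$Ds + outgroup_D$Ds_extra
    mk$genes$Dn <- mk$genes$Dn + outgroup_D$Dn_extra
  }
  mk
}

#' Draw per-gene outgroup-lineage divergence for truth-route MK tables
#'
#' One Poisson draw per gene and class of the fixed differences
#' contributed by the outgroup branch, with divergence at selected
#' positions scaled down to emulate purifying selection. All populations
#' compared against the same outgroup share one branch, so one draw per
#' replicate should be reused across populations (see
#' [sim_mk_tables()]).
#'
#' @param layout a [genome_layout()].
#' @param divergence per-site substitution rate at synonymous-like sites.
#' @param nonsyn_divergence_ratio multiplier at selected sites.
#' @return data.table with `gene_id`, `Dn_extra`, `Ds_extra`.
#' @export
draw_outgroup_mk_divergence <- function(layout, divergence,
                                        nonsyn_divergence_ratio = 0.25) {
  n_sites <- layout$cds_length
  n_sel <- round(n_sites * layout$deleterious_fraction)
  n_neu <- n_sites - n_sel
  data.table::data.table(
    gene_id = sprintf("g%05d", seq_len(layout$n_cds)),
    Dn_extra = stats::rpois(layout$n_cds,
                            divergence * nonsyn_divergence_ratio * n_sel),
    Ds_extra = stats::rpois(layout$n_cds, divergence * n_neu))
}
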