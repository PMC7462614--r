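#' Forward Wright-Fisher simulation with selection
#'
#' Simulates a diploid Wright-Fisher population (optionally splitting into
#' daughter populations following a [build_demography()] plan) on the
#' genome described by the configuration's [genome_layout()]. Each
#' generation, parents are sampled with probability proportional to
#' fitness (multiplicative across sites; heterozygotes 1 + h s,
#' homozygotes 1 + s), gametes recombine by Poisson crossovers, and new
#' mutations arise at rate `mutation_rate` per coding bp under the
#' infinite-sites model: neutral mutations at neutral-class positions and
#' gamma-distributed deleterious mutations at selected-class positions.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_output`: a `mutations` table (0-based
#'   `pos`, `s`, `h`, `class`, `origin`), per-population lists with
#'   segregating mutation frequencies, fixed mutations (since the split),
#'   and a sampled diploid genotype matrix, plus the ids of mutations
#'   fixed in the common ancestor.
#' @export
simulate_forward <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  layout <- config$layout
  L <- genome_length(layout)
  classes <- layout_site_classes(layout)
  mutable <- which(classes > 0L) - 1L  # 0-based
  mutable_class <- classes[classes > 0L]

  gm <- config$dfe$gamma_mean
  if (identical(config$dfe$scale, "2Ns")) {
    n_anc <- if (is.null(config$demography)) config$constant_size else
      config$demography$ancestral_size
    gm <- gm / (2 * n_anc)
  }

  if (is.null(config$demography)) {
    phase1 <- rep(config$constant_size, config$constant_generations + 1L)
    phase2 <- matrix(integer(0), nrow = 0, ncol = 1)
    pop_names <- "pop1"
  } else {
    d <- config$demography
    phase1 <- rep(d$ancestral_size, d$burn_in + d$split_generation + 1L)
    phase2 <- d$trajectory
    pop_names <- paste0("pop", seq_len(ncol(phase2)))
  }

  set.seed(config$seed)
  raw <- .wf_simulate(as.integer(L), as.integer(mutable),
                      as.integer(mutable_class),
                      config$mutation_rate, config$recombination_rate,
                      gm, config$dfe$gamma_shape, config$dfe$dominance,
                      as.integer(phase1), phase2,
                      config$sample_n, 50L, config$mutation_cap)

  muts <- data.table::data.table(
    id = seq_along(raw$pos),
    pos = raw$pos,
    s = raw$s,
    h = ifelse(raw$class == 2L, config$dfe$dominance, 0.5),
    class = ifelse(raw$class == 2L, "deleterious", "neutral"),
    origin = raw$origin)

  pops <- vector("list", length(raw$populations))
  names(pops) <- pop_names
  for (p in seq_along(pops)) {
    rp <- raw$populations[[p]]
    seg <- data.table::data.table(
      id = rp$seg_idx,
      pos = raw$pos[rp$seg_idx],
      s = raw$s[rp$seg_idx],
      class = ifelse(raw$class[rp$seg_idx] == 2L, "deleterious", "neutral"),
      count = rp$seg_count,
      freq = rp$seg_count / (2 * rp$n_diploid))
    geno <- rp$sample_geno
    rownames(geno) <- as.character(rp$seg_idx)
    pops[[p]] <- list(n_diploid = rp$n_diploid,
                      segregating = seg,
                      fixed_idx = rp$fixed_idx,
                      sample_geno = geno)
  }

  structure(list(mutations = muts,
                 populations = pops,
                 anc_fixed_idx = raw$anc_fixed_idx,
                 n_mutations_total = raw$n_mutations_total,
                 config = config),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("sim_output: %d population(s), genome %d bp, seed %d\n",
              length(x$populations), genome_length(x$config$layout),
              x$config$seed))
  for (nm in names(x$populations)) {
    p <- x$populations[[nm]]
    cat(sprintf("  %s: N = %d, %d segregating, %d fixed since split\n",
                nm, p$n_diploid, nrow(p$segregating), length(p$fixed_idx)))
  }
  cat(sprintf("  %d mutations fixed in the common ancestor\n",
              length(x$anc_fixed_idx)))
  invisible(x)
}

#' Mutations fixed in a population relative to the reference
#'
#' Union of mutations fixed before the split (shared by all daughters) and
#' those fixed in the focal population since the split.
#'
#' @param sim a `sim_output`.
#' @param pop population name or index.
#' @return subset of `sim$mutations`.
#' @export
fixed_mutations <- function(sim, pop) {
  idx <- sort(unique(c(sim$anc_fixed_idx, sim$populations[[pop]]$fixed_idx)))
  sim$mutations[idx]
}

#' Sample allele frequencies of a population, including fixed sites
#'
#' Derived allele frequencies in the sampled diploids, with fixed
#' mutations included at frequency 1; used to emit pooled read counts.
#'
#' @param sim a `sim_output`.
#' @param pop population name or index.
#' @return data.table with `pos`, `id`, `freq` (in the sample), `class`,
#'   `s`.
#' @export
sample_site_frequencies <- function(sim, pop) {
  p <- sim$populations[[pop]]
  n_chrom <- 2 * ncol(p$sample_geno)
  seg <- data.table::data.table(
    id = p$segregating$id,
    pos = p$segregating$pos,
    class = p$segregating$class,
    s = p$segregating$s,
    freq = rowSums(p$sample_geno) / n_chrom)
  fx <- fixed_mutations(sim, pop)
  fxd <- data.table::data.table(id = fx$id, pos = fx$pos, class = fx$class,
                                s = fx$s, freq = 1)
  out <- rbind(seg[freq > 0], fxd)
  data.table::setorder(out, pos)
  out
}
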