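#' Genome layout for forward simulation
#'
#' Describes a synthetic genome of `n_cds` coding sequences of
#' `cds_length` bp separated by `spacer_length` bp of non-coding sequence.
#' Coding positions follow a codon-like 3-periodic pattern in which a
#' fraction `neutral_fraction` of positions accept neutral
#' (synonymous-like) mutations and the remaining `deleterious_fraction`
#' accept selected (non-synonymous-like) mutations. With the default 1/3
#' neutral fraction the third position of every codon is the neutral one,
#' mirroring the degeneracy structure of real coding sequence.
#'
#' @param n_cds number of coding sequences.
#' @param cds_length length of each coding sequence in bp (multiple of 3).
#' @param spacer_length non-coding bp between consecutive CDS.
#' @param neutral_fraction fraction of coding positions that are neutral.
#' @param deleterious_fraction fraction that are under selection; must sum
#'   to 1 with `neutral_fraction`.
#' @return an object of class `genome_layout`.
#' @export
genome_layout <- function(n_cds = 1500, cds_length = 500, spacer_length = 100,
                          neutral_fraction = 1 / 3,
                          deleterious_fraction = 1 - neutral_fraction) {
  stopifnot(n_cds >= 1, cds_length >= 3, spacer_length >= 0)
  if (abs(neutral_fraction + deleterious_fraction - 1) > 1e-8)
    stop("neutral_fraction + deleterious_fraction must equal 1")
  if (neutral_fraction < 0 || neutral_fraction > 1)
    stop("neutral_fraction must lie in [0, 1]")
  structure(list(n_cds = as.integer(n_cds),
                 cds_length = as.integer(cds_length),
                 spacer_length = as.integer(spacer_length),
                 neutral_fraction = neutral_fraction,
                 deleterious_fraction = deleterious_fraction),
            class = "genome_layout")
}

#' Total genome length implied by a layout
#' @param layout a [genome_layout()].
#' @return genome length in bp.
#' @export
genome_length <- function(layout) {
  layout$n_cds * (layout$cds_length + layout$spacer_length)
}

#' Per-position mutation classes of a layout
#'
#' @param layout a [genome_layout()].
#' @return integer vector over the genome: 0 non-coding, 1 neutral coding,
#'   2 selected coding. Within each codon, slots are neutral when
#'   `slot/3 > 1 - neutral_fraction`, so a neutral fraction of 1/3 makes
#'   the third slot of every codon neutral.
#' @export
layout_site_classes <- function(layout) {
  unit <- layout$cds_length + layout$spacer_length
  slot <- (seq_len(layout$cds_length) - 1L) %% 3L  # 0,1,2 within codon
  n_del_slots <- round(3 * layout$deleterious_fraction)
  coding <- ifelse(slot < n_del_slots, 2L, 1L)
  unit_classes <- c(coding, rep(0L, layout$spacer_length))
  rep(unit_classes, layout$n_cds)
}

#' Distribution of fitness effects of new selected mutations
#'
#' Selection coefficients of selected-class mutations are drawn from a
#' reflected gamma distribution: s = -g with g ~ Gamma(shape,
#' scale = |mean|/shape), so that E[s] = `gamma_mean`. A `gamma_mean` of 0
#' makes every selected-class mutation effectively neutral (s = 0), which
#' is useful for null checks.
#'
#' @param gamma_mean mean selection coefficient (<= 0).
#' @param gamma_shape gamma shape parameter (> 0).
#' @param dominance dominance coefficient h in \[0, 1\]; heterozygote
#'   fitness is 1 + h s, homozygote fitness 1 + s.
#' @param scale interpretation of `gamma_mean`: `"s"` (default) reads it
#'   as the unscaled coefficient; `"2Ns"` divides by 2N at simulation
#'   time, with N the ancestral size.
#' @return an object of class `dfe_params`.
#' @export
dfe_params <- function(gamma_mean = -2.5, gamma_shape = 0.35,
                       dominance = 0.1, scale = c("s", "2Ns")) {
  scale <- match.arg(scale)
  if (gamma_mean > 0) stop("gamma_mean must be <= 0")
  if (gamma_shape <= 0) stop("gamma_shape must be > 0")
  if (dominance < 0 || dominance > 1) stop("dominance must lie in [0, 1]")
  structure(list(gamma_mean = gamma_mean, gamma_shape = gamma_shape,
                 dominance = dominance, scale = scale),
            class = "dfe_params")
}

#' Draw selection coefficients from a reflected gamma DFE
#'
#' @param n number of draws.
#' @param dfe a [dfe_params()] (interpreted on the s scale).
#' @return numeric vector of selection coefficients (all <= 0).
#' @export
draw_selection_coefficient <- function(n, dfe) {
  stopifnot(inherits(dfe, "dfe_params"))
  if (dfe$gamma_mean == 0) return(rep(0, n))
  -stats::rgamma(n, shape = dfe$gamma_shape,
                 scale = -dfe$gamma_mean / dfe$gamma_shape)
}

#' Demographic plan: ancestral population splitting into daughters
#'
#' Builds the per-generation population-size trajectories for the four
#' two-population scenarios used throughout the package, all of which
#' start from a common ancestral population of constant size:
#' \describe{
#'   \item{A}{split at `split_generation` > 0, then an immediate size
#'     change of each daughter to its target, constant afterwards.}
#'   \item{B}{split immediately after burn-in (`split_generation` = 0),
#'     immediate size change, constant afterwards.}
#'   \item{C}{split at `split_generation` > 0, then exponential growth (or
#'     decline) towards the target size, reached exactly at
#'     `total_generations`.}
#'   \item{D}{split immediately after burn-in with exponential growth.}
#' }
#' `"custom"` accepts an explicit list of per-daughter trajectories.
#'
#' @param model_id one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param ancestral_size diploid size of the ancestral population.
#' @param daughter_sizes integer vector of target diploid sizes, one per
#'   daughter population (two for the standard models).
#' @param split_generation generations after burn-in at which the split
#'   occurs; must be 0 for models B and D.
#' @param total_generations generations simulated after burn-in.
#' @param burn_in burn-in generations at the ancestral size.
#' @return an object of class `demography_plan` with the full size
#'   trajectory of every population.
#' @export
build_demography <- function(model_id, ancestral_size, daughter_sizes,
                             split_generation, total_generations,
                             burn_in = 50000) {
  if (!model_id %in% c("A", "B", "C", "D"))
    stop("unknown model_id: ", model_id)
  daughter_sizes <- as.integer(daughter_sizes)
  if (any(daughter_sizes < 2) || ancestral_size < 2)
    stop("population sizes must be >= 2")
  if (split_generation < 0 || split_generation > total_generations)
    stop("split_generation must lie in [0, total_generations]")
  if (model_id %in% c("B", "D") && split_generation != 0)
    stop("models B and D split directly after burn-in (split_generation = 0)")
  n_pop <- length(daughter_sizes)
  post <- total_generations - split_generation
  if (post < 1) stop("at least one generation after the split is required")

  traj <- matrix(0L, nrow = post, ncol = n_pop)
  for (p in seq_len(n_pop)) {
    if (model_id %in% c("A", "B")) {
      traj[, p] <- daughter_sizes[p]
    } else {
      # exponential path from the ancestral size, hitting the target
      # exactly at the final generation
      r <- log(daughter_sizes[p] / ancestral_size) / post
      traj[, p] <- as.integer(round(ancestral_size * exp(r * seq_len(post))))
    }
  }
  structure(list(model_id = model_id,
                 ancestral_size = as.integer(ancestral_size),
                 daughter_sizes = daughter_sizes,
                 burn_in = as.integer(burn_in),
                 split_generation = as.integer(split_generation),
                 total_generations = as.integer(total_generations),
                 trajectory = traj),
            class = "demography_plan")
}

#' @export
print.demography_plan <- function(x, ...) {
  cat(sprintf("demography_plan model %s: ancestral N = %d, burn-in %d\n",
              x$model_id, x$ancestral_size, x$burn_in))
  cat(sprintf("  split %d generations after burn-in; %d generations total\n",
              x$split_generation, x$total_generations))
  cat(sprintf("  %d daughter population(s), final sizes: %s\n",
              ncol(x$trajectory),
              paste(x$trajectory[nrow(x$trajectory), ], collapse = ", ")))
  invisible(x)
}

#' Full configuration of a forward simulation
#'
#' Defaults are the rescaled study conditions: an ancestral population of
#' 10,000 diploids, 1500 coding sequences of 500 bp, mutation rate
#' 5.468928e-8 and recombination rate 6.604764e-6 per bp per generation,
#' a reflected-gamma DFE with mean -2.5 and shape 0.35, dominance 0.1,
#' and a 50,000-generation burn-in.
#'
#' @param layout a [genome_layout()].
#' @param dfe a [dfe_params()].
#' @param demography a [build_demography()] plan, or `NULL` for a single
#'   constant population (useful for neutral checks).
#' @param mutation_rate per bp per generation.
#' @param recombination_rate per bp per generation.
#' @param seed integer master seed for the replicate.
#' @param sample_n diploid individuals sampled per population at the end.
#' @param constant_size,constant_generations single-population fallback
#'   used when `demography` is `NULL`.
#' @param mutation_cap hard cap on the number of mutation records
#'   (memory guard).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(layout = genome_layout(),
                       dfe = dfe_params(),
                       demography = NULL,
                       mutation_rate = 5.468928e-8,
                       recombination_rate = 6.604764e-6,
                       seed = 1L,
                       sample_n = 30L,
                       constant_size = 10000L,
                       constant_generations = 50000L,
                       mutation_cap = 2e7) {
  stopifnot(inherits(layout, "genome_layout"), inherits(dfe, "dfe_params"))
  if (mutation_rate < 0 || recombination_rate < 0)
    stop("rates must be >= 0")
  structure(list(layout = layout, dfe = dfe, demography = demography,
                 mutation_rate = mutation_rate,
                 recombination_rate = recombination_rate,
                 seed = as.integer(seed), sample_n = as.integer(sample_n),
                 constant_size = as.integer(constant_size),
                 constant_generations = as.integer(constant_generations),
                 mutation_cap = mutation_cap),
            class = "sim_config")
}

#' Rescale a simulation configuration to a smaller population size
#'
#' Standard population-genetic rescaling: dividing N by `factor` while
#' multiplying the mutation and recombination rates by `factor` preserves
#' the scaled parameters 4Nu and 4Nr; generation counts (burn-in, split
#' times) shrink by the same factor so that times in units of N are
#' preserved.
#'
#' @param config a [sim_config()].
#' @param factor rescaling factor (> 1 shrinks the population).
#' @return a rescaled `sim_config`.
#' @export
rescale_sim_config <- function(config, factor) {
  stopifnot(inherits(config, "sim_config"), factor > 0)
  config$mutation_rate <- config$mutation_rate * factor
  config$recombination_rate <- config$recombination_rate * factor
  config$constant_size <- max(2L, as.integer(round(config$constant_size / factor)))
  config$constant_generations <-
    max(1L, as.integer(round(config$constant_generations / factor)))
  if (!is.null(config$demography)) {
    d <- config$demography
    config$demography <- build_demography(
      d$model_id,
      max(2L, round(d$ancestral_size / factor)),
      pmax(2L, round(d$daughter_sizes / factor)),
      round(d$split_generation / factor),
      max(1L, round(d$total_generations / factor)),
      burn_in = max(1L, round(d$burn_in / factor)))
  }
  config
}
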