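# Shared simulation fixtures, memoised so heavy runs happen once per
# session regardless of how many test files use them.

.sim_cache <- new.env(parent = emptyenv())

# Paired small-N / large-N replicate experiment (desk scale).
#
# Study design: ancestral population of 500 diploids splitting right
# after a 5N burn-in into daughters of 50 and 500 (1:10), evolved for a
# further 250 generations; 40 coding genes of 3000 bp; reflected-gamma
# DFE (mean -2.5, shape 0.35, h = 0.1); mutation supply chosen so that
# genes carry several polymorphic sites each, as in the full-scale data.
# Per replicate and population: median per-gene DoS (with an outgroup
# lineage divergence of 0.01 at synonymous-like sites) and the fraction
# of segregating selected mutations in the nearly-neutral band.
paired_experiment <- function(n_rep = 25, base_seed = 101) {
  key <- sprintf("paired_%d_%d", n_rep, base_seed)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  rows <- vector("list", 2 * n_rep)
  for (r in seq_len(n_rep)) {
    lay <- genome_layout(n_cds = 40, cds_length = 3000, spacer_length = 300)
    dem <- build_demography("B", 500, c(50, 500), 0, 250, burn_in = 2500)
    cfg <- sim_config(layout = lay, dfe = dfe_params(-2.5, 0.35, 0.1),
                      demography = dem, mutation_rate = 1e-5,
                      recombination_rate = 1.3e-5,
                      seed = base_seed + r, sample_n = 30)
    sim <- simulate_forward(cfg)
    # one outgroup branch, shared by both daughter populations
    og_D <- draw_outgroup_mk_divergence(lay, 0.01)
    for (p in 1:2) {
      N <- sim$populations[[p]]$n_diploid
      seg <- sim$populations[[p]]$segregating
      ns <- seg[seg$class == "deleterious", ]
      d <- dos(sim_mk_tables(sim, p, outgroup_D = og_D)$genes)
      rows[[2 * (r - 1) + p]] <- data.frame(
        rep = r, pop = c("small", "large")[p], N = N,
        median_dos = stats::median(d, na.rm = TRUE),
        n_dos = sum(!is.na(d)),
        nn1 = mean(abs(4 * N * ns$s) < 1),
        nn10 = mean(abs(4 * N * ns$s) < 10),
        n_seg_ns = nrow(ns))
    }
  }
  out <- do.call(rbind, rows)
  .sim_cache[[key]] <- out
  out
}

# Mean window F_ST of two neutral populations after increasing split
# times (memoised; used for the divergence-monotonicity checks).
fst_split_series <- function(posts = c(100, 400, 1600), seeds = 41:43) {
  key <- paste0("fst_series_", paste(posts, collapse = "_"))
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  one <- function(post, seed) {
    L <- 49998
    lay <- genome_layout(n_cds = 1, cds_length = L, spacer_length = 0,
                         neutral_fraction = 1)
    dem <- build_demography("B", 300, c(300, 300), 0, post, burn_in = 1500)
    cfg <- sim_config(layout = lay, dfe = dfe_params(gamma_mean = 0),
                      demography = dem, mutation_rate = 2e-6,
                      recombination_rate = 1e-6, seed = seed, sample_n = 30)
    sim <- simulate_forward(cfg)
    counts <- lapply(1:2, function(p) {
      fr <- sample_site_frequencies(sim, p)
      fvec <- rep(0, L)
      fvec[fr$pos + 1] <- fr$freq
      pool_reads(fvec, rep("A", L), rep("G", L), depth = 100)
    })
    w <- window_fst(counts[[1]], counts[[2]], pos = 1:L,
                    window_size = 10000, min_depth = 20)
    mean(w$fst, na.rm = TRUE)
  }
  out <- mapply(one, posts, seeds)
  .sim_cache[[key]] <- out
  out
}

# Small two-population study system written to disk, with sequencing
# error, used by the pipeline tests.
pipeline_fixture <- function() {
  if (!is.null(.sim_cache$fixture)) return(.sim_cache$fixture)
  lay <- genome_layout(n_cds = 40, cds_length = 300, spacer_length = 100)
  dem <- build_demography("B", 400, c(80, 400), 0, 300, burn_in = 2000)
  cfg <- sim_config(layout = lay, dfe = dfe_params(-2.5, 0.35, 0.1),
                    demography = dem, mutation_rate = 2e-6,
                    recombination_rate = 1e-5, seed = 500, sample_n = 30)
  sim <- simulate_forward(cfg)
  dir <- file.path(tempdir(), "ppg_fixture")
  set.seed(77)
  paths <- write_sim_fixtures(sim, dir, depth = 80, error_rate = 0.002,
                              divergence = 0.03)
  res <- list(sim = sim, paths = paths, dir = dir)
  .sim_cache$fixture <- res
  res
}

# Deep-coverage, error-free fixture with the outgroup equal to the
# ancestor, used for the polarization-recovery check.
clean_fixture <- function() {
  if (!is.null(.sim_cache$clean)) return(.sim_cache$clean)
  lay <- genome_layout(n_cds = 30, cds_length = 300, spacer_length = 60)
  cfg <- sim_config(layout = lay, dfe = dfe_params(gamma_mean = 0),
                    demography = NULL, mutation_rate = 5e-6,
                    recombination_rate = 1e-5, seed = 61, sample_n = 30,
                    constant_size = 300, constant_generations = 1500)
  sim <- simulate_forward(cfg)
  dir <- file.path(tempdir(), "ppg_clean")
  set.seed(62)
  paths <- write_sim_fixtures(sim, dir, depth = 200, error_rate = 0,
                              divergence = 0)
  res <- list(sim = sim, paths = paths, dir = dir)
  .sim_cache$clean <- res
  res
}
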