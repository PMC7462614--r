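test_that("demography plans follow the four model definitions", {
  pA <- build_demography("A", 10000, c(10000, 1000), 25000, 50000)
  expect_equal(nrow(pA$trajectory), 25000)
  expect_true(all(pA$trajectory[, 1] == 10000))
  expect_true(all(pA$trajectory[, 2] == 1000))

  pB <- build_demography("B", 10000, c(10000, 10000), 0, 50000)
  expect_true(all(pB$trajectory == 10000))

  pC <- build_demography("C", 10000, c(10000, 100000), 0, 46050)
  r <- log(10) / 46050
  expect_equal(pC$trajectory[1, 2], round(10000 * exp(r)))
  expect_lte(abs(pC$trajectory[46050, 2] - 100000), 1)
  expect_true(all(diff(pC$trajectory[, 2]) >= 0))

  expect_error(build_demography("E", 100, c(50, 50), 0, 100), "unknown")
  expect_error(build_demography("B", 100, c(50, 50), 10, 100), "split")
  expect_error(build_demography("A", 100, c(1, 50), 0, 100), ">= 2")
})

test_that("reflected-gamma draws match the stated moments", {
  dfe <- dfe_params(gamma_mean = -2.5, gamma_shape = 0.35)
  set.seed(1)
  s <- draw_selection_coefficient(1e6, dfe)
  expect_true(all(s < 0))
  expect_gt(mean(s), -2.52)
  expect_lt(mean(s), -2.48)
  # Var = mean^2 / shape
  expect_lt(abs(stats::var(s) - 2.5^2 / 0.35) / (2.5^2 / 0.35), 0.05)
  expect_true(all(draw_selection_coefficient(10, dfe_params(0)) == 0))
})

test_that("segregating and fixed mutation sets are disjoint and samples are valid", {
  lay <- genome_layout(n_cds = 20, cds_length = 300, spacer_length = 60)
  dem <- build_demography("B", 200, c(60, 200), 0, 200, burn_in = 1000)
  cfg <- sim_config(layout = lay, dfe = dfe_params(-2.5, 0.35, 0.1),
                    demography = dem, mutation_rate = 3e-6,
                    recombination_rate = 1e-5, seed = 9, sample_n = 30)
  sim <- simulate_forward(cfg)
  for (p in 1:2) {
    pop <- sim$populations[[p]]
    fixed <- unique(c(sim$anc_fixed_idx, pop$fixed_idx))
    expect_length(intersect(pop$segregating$id, fixed), 0)
    expect_true(all(pop$segregating$freq > 0 & pop$segregating$freq < 1))
    expect_true(all(pop$sample_geno %in% 0:2))
    expect_equal(ncol(pop$sample_geno), 30)
    # class labels agree with selection coefficients
    expect_true(all((sim$mutations$s == 0) ==
                      (sim$mutations$class == "neutral")))
  }
})

test_that("identical seeds give bit-identical simulations", {
  cfg <- sim_config(layout = genome_layout(5, 300, 60),
                    dfe = dfe_params(-2.5, 0.35, 0.1),
                    mutation_rate = 3e-6, recombination_rate = 1e-5,
                    seed = 33, sample_n = 10,
                    constant_size = 100, constant_generations = 300)
  s1 <- simulate_forward(cfg)
  s2 <- simulate_forward(cfg)
  expect_identical(s1$mutations, s2$mutations)
  expect_identical(s1$populations[[1]]$sample_geno,
                   s2$populations[[1]]$sample_geno)
})

test_that("neutral fixation count matches the 1/(2N) expectation", {
  # mu * L * T substitutions expected at equilibrium
  cfg <- sim_config(layout = genome_layout(1, 1998, 0, neutral_fraction = 1),
                    dfe = dfe_params(gamma_mean = 0),
                    mutation_rate = 1e-5, recombination_rate = 0,
                    seed = 21, sample_n = 10,
                    constant_size = 50, constant_generations = 3000)
  sim <- simulate_forward(cfg)
  n_fixed <- length(sim$anc_fixed_idx)
  expected <- 1e-5 * 1998 * 3000  # ~60
  expect_gt(n_fixed, expected * 0.5)
  expect_lt(n_fixed, expected * 1.6)
})

test_that("with s = 0 and h = 0.5 the selected class behaves neutrally", {
  lay <- genome_layout(n_cds = 10, cds_length = 1500, spacer_length = 0)
  cfg <- sim_config(layout = lay,
                    dfe = dfe_params(gamma_mean = 0, dominance = 0.5),
                    mutation_rate = 5e-6, recombination_rate = 1e-5,
                    seed = 13, sample_n = 10,
                    constant_size = 200, constant_generations = 2000)
  sim <- simulate_forward(cfg)
  seg <- sim$populations[[1]]$segregating
  f_neu <- seg$freq[seg$class == "neutral"]
  f_del <- seg$freq[seg$class == "deleterious"]
  expect_gt(length(f_neu), 30)
  expect_gt(length(f_del), 30)
  p <- suppressWarnings(stats::ks.test(f_neu, f_del)$p.value)
  expect_gt(p, 0.01)
})

test_that("pooled read sampling follows the binomial error model", {
  set.seed(4)
  # deep pool at frequency 0.5, no error
  cm <- pool_reads(rep(0.5, 1), "A", "G", depth = 1e6, error_rate = 0)
  f <- cm[1, "G"] / sum(cm[1, ])
  expect_gt(f, 0.498); expect_lt(f, 0.502)
  # monomorphic, no error: single allele only
  cm <- pool_reads(rep(0, 50), rep("T", 50), rep("T", 50), depth = 30)
  expect_true(all(cm[, c("A", "C", "G")] == 0))
  # error model: non-reference fraction ~ error rate
  cm <- pool_reads(0, "A", "A", depth = 1e5, error_rate = 0.01)
  frac <- sum(cm[1, c("C", "G", "T")]) / sum(cm[1, ])
  se <- sqrt(0.01 * 0.99 / 1e5)
  expect_lt(abs(frac - 0.01), 3 * se)
  expect_error(pool_reads(numeric(0), character(0), character(0), 10),
               "empty")
  expect_error(pool_reads(0.5, "A", "G", 10, error_rate = 0.3), "error_rate")
})

test_that("outgroup divergence is Jukes-Cantor-like at the stated rate", {
  set.seed(8)
  ref <- paste0(sample(c("A", "C", "G", "T"), 2e5, replace = TRUE),
                collapse = "")
  expect_identical(mutate_outgroup(ref, 0)$sequence, ref)
  og <- mutate_outgroup(ref, 0.02)
  expect_equal(nchar(og$sequence), nchar(ref))
  frac <- length(og$positions) / nchar(ref)
  se <- sqrt(0.02 * 0.98 / 2e5)
  expect_lt(abs(frac - 0.02), 3 * se)
  # every substituted position differs from the reference
  rv <- strsplit(ref, "")[[1]]
  ov <- strsplit(og$sequence, "")[[1]]
  expect_true(all(rv[og$positions + 1] != ov[og$positions + 1]))
  expect_true(all(rv[-(og$positions + 1)] == ov[-(og$positions + 1)]))
})

test_that("small populations carry relatively more nearly-neutral selected variants", {
  exp_dt <- paired_experiment()
  small <- exp_dt[exp_dt$pop == "small", ]
  large <- exp_dt[exp_dt$pop == "large", ]
  # |4Ns| < 1 and < 10 bands, paired one-sided Wilcoxon over replicates
  for (band in c("nn1", "nn10")) {
    p <- stats::wilcox.test(small[[band]], large[[band]], paired = TRUE,
                            alternative = "greater")$p.value
    expect_lt(p, 0.05)
  }
})
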