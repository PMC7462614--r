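test_that("SFS construction bins polymorphic sites and counts divergence", {
  pol <- data.table::data.table(
    daf = c(0.5, 0.5, 0.1, 0.97, 1, 0.02),
    status = c("polymorphic", "polymorphic", "polymorphic", "fixed",
               "fixed", "monomorphic"))
  s <- build_sfs(pol, n = 10, class = "synonymous")
  expect_equal(sum(s$counts), 3)
  expect_equal(s$counts[["5"]], 2)
  expect_equal(s$counts[["1"]], 1)
  expect_equal(s$fixed, 2)
  expect_equal(s$n, 10L)
})

test_that("hypergeometric projection matches the pmf oracle and conserves mass", {
  # single-entry spectrum: the worked example
  s <- as_sfs(c(rep(0, 14), 184756, rep(0, 14)))
  p <- project_sfs(s, 10)
  expect_equal(p$counts[["5"]], 184756 * stats::dhyper(5, 15, 15, 10),
               tolerance = 1e-12)
  expect_equal(sum(p$counts) + p$dropped_zero + p$dropped_fixed, 184756,
               tolerance = 1e-9)
  # projecting to the native size is the identity
  s2 <- as_sfs(c(5, 3, 2, 1))
  expect_equal(project_sfs(s2, 5)$counts, s2$counts)
  expect_error(project_sfs(s2, 6), "exceed")
  expect_error(project_sfs(s2, 1), ">= 2")
  # mass conservation on random spectra
  set.seed(30)
  for (r in 1:20) {
    n <- sample(10:60, 1)
    m <- sample(2:n, 1)
    cs <- stats::rpois(n - 1, 50)
    pr <- project_sfs(as_sfs(cs), m)
    expect_equal(sum(pr$counts) + pr$dropped_zero + pr$dropped_fixed,
                 sum(cs), tolerance = 1e-9)
    # every class matches the pmf oracle
    for (i in seq_len(m - 1)) {
      want <- sum(cs * stats::dhyper(i, seq_len(n - 1),
                                     n - seq_len(n - 1), m))
      expect_equal(pr$counts[[i]], want, tolerance = 1e-9)
    }
  }
})

test_that("the expected SFS has the analytic neutral form and selection limits", {
  i <- 1:9
  expect_equal(expected_sfs(0, 10, 10), 10 / i)
  # continuity at S -> 0
  expect_lt(max(abs(expected_sfs(1e-8, 10, 10) - 10 / i)), 1e-6)
  # strong purifying selection drops high-frequency classes faster
  e <- expected_sfs(-50, 1, 10)
  expect_true(all(diff(e) < 0))
  expect_lt(e[9] / e[1], 1 / 9)
  # deep-negative asymptotic branch joins the quadrature branch
  e1 <- expected_sfs(-499, 1, 10)
  e2 <- expected_sfs(-501, 1, 10)
  expect_equal(e1, e2, tolerance = 0.05)
})

test_that("the gamma DFE likelihood recovers the shape parameter", {
  n <- 10
  gen_sfs <- function(shape, meanS, theta_L, K = 400) {
    q <- stats::qgamma((seq_len(K) - 0.5) / K, shape = shape,
                       scale = meanS / shape)
    rowMeans(vapply(q, function(s) expected_sfs(-s, theta_L, n),
                    numeric(n - 1)))
  }
  lam_ns <- gen_sfs(0.35, 500, 2500)
  lam_s <- 2500 / (1:9)
  set.seed(31)
  shapes <- replicate(3, {
    f <- suppressWarnings(fit_gamma_dfe(
      as_sfs(stats::rpois(9, lam_s * 400)),
      as_sfs(stats::rpois(9, lam_ns * 400)), n_boot = 0))
    f$shape
  })
  expect_true(all(shapes > 0.2 & shapes < 0.5))
})

test_that("neutral data drive the deleterious model to the neutral likelihood", {
  set.seed(32)
  i <- 1:9
  Fs <- stats::rpois(9, 5000 / i)
  Fn <- stats::rpois(9, 5000 / i)
  fit <- suppressWarnings(fit_gamma_dfe(as_sfs(Fs), as_sfs(Fn), n_boot = 0))
  # profile neutral likelihood of the non-synonymous spectrum
  th <- sum(Fn) / sum(1 / i)
  ll_neutral <- sum(Fn * log(th / i) - th / i)
  th_s <- sum(Fs) / sum(1 / i)
  ll_neutral <- ll_neutral + sum(Fs * log(th_s / i) - th_s / i)
  expect_lt(abs(-2 * fit$logLik - (-2 * ll_neutral)), 2)
})

test_that("AIC model choice prefers fewer parameters on likelihood ties", {
  f1 <- structure(list(model = "del", AIC = 2 * 4 - 2 * 100,
                       n_params = 4, logLik = 100), class = "dfe_fit")
  f2 <- structure(list(model = "del_neut", AIC = 2 * 5 - 2 * 100,
                       n_params = 5, logLik = 100), class = "dfe_fit")
  expect_equal(compare_models_aic(list(f2, f1))$model, "del")
  # genuinely better likelihood wins despite the extra parameter
  f3 <- structure(list(model = "del_neut", AIC = 2 * 5 - 2 * 110,
                       n_params = 5, logLik = 110), class = "dfe_fit")
  expect_equal(compare_models_aic(list(f1, f3))$model, "del_neut")
})
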