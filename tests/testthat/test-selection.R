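make_pol <- function(gene = "g1",
                     n_fix0 = 0, n_fix4 = 0,
                     daf0 = numeric(0), daf4 = numeric(0)) {
  data.table::data.table(
    gene_id = gene,
    degeneracy = c(rep("zero_fold", n_fix0), rep("four_fold", n_fix4),
                   rep("zero_fold", length(daf0)),
                   rep("four_fold", length(daf4))),
    daf = c(rep(1, n_fix0 + n_fix4), daf0, daf4),
    status = c(rep("fixed", n_fix0 + n_fix4),
               rep("polymorphic", length(daf0) + length(daf4))))
}

test_that("MK tables tally fixed and polymorphic sites per gene", {
  pol <- make_pol(n_fix0 = 2, n_fix4 = 1,
                  daf0 = c(0.1, 0.4, 0.8), daf4 = c(0.2, 0.5, 0.9))
  mk <- mk_counts(pol)
  expect_equal(unlist(mk$genes[, .(Dn, Ds, Pn, Ps)]),
               c(Dn = 2L, Ds = 1L, Pn = 3L, Ps = 3L))
  expect_equal(sum(mk$Pn_x), 3)
  expect_equal(sum(mk$Ps_x), 3)
  # a site at daf 0.97 has status "fixed" and feeds Dn only
  pol2 <- rbind(pol, data.table::data.table(
    gene_id = "g1", degeneracy = "zero_fold", daf = 0.97,
    status = "fixed"))
  mk2 <- mk_counts(pol2)
  expect_equal(mk2$genes$Dn, 3L)
  expect_equal(mk2$genes$Pn, 3L)
  # 2-fold sites are ignored entirely
  pol3 <- rbind(pol, data.table::data.table(
    gene_id = "g1", degeneracy = "other", daf = 0.5,
    status = "polymorphic"))
  expect_equal(mk_counts(pol3)$genes, mk$genes)
})

test_that("alpha(x) follows the binned MK formula", {
  bins <- daf_bins()
  # neutral identity: Dn = Ds, Pn(x) = Ps(x) -> alpha = 0 everywhere
  mkn <- list(Dn = 50, Ds = 50, Pn_x = rep(10, 9), Ps_x = rep(10, 9),
              bins = bins)
  expect_equal(alpha_x(mkn)$alpha, rep(0, 9))
  # arithmetic example
  mk1 <- list(Dn = 20, Ds = 10, Pn_x = rep(5, 9), Ps_x = rep(10, 9),
              bins = bins)
  expect_equal(alpha_x(mk1)$alpha, rep(0.75, 9))
  # low-frequency deleterious excess gives a depressed left tail
  mk2 <- list(Dn = 10, Ds = 10, Pn_x = c(30, rep(10, 8)),
              Ps_x = rep(10, 9), bins = bins)
  expect_equal(alpha_x(mk2)$alpha[1], -2)
  # zero-denominator bins are missing; Dn = 0 is an error
  mk3 <- list(Dn = 10, Ds = 10, Pn_x = rep(1, 9),
              Ps_x = c(0, rep(5, 8)), bins = bins)
  expect_true(is.na(alpha_x(mk3)$alpha[1]))
  mk4 <- list(Dn = 0, Ds = 10, Pn_x = rep(1, 9), Ps_x = rep(1, 9),
              bins = bins)
  expect_error(alpha_x(mk4), "Dn")
})

test_that("the asymptotic fit recovers exact exponential curves", {
  x <- daf_bins()$mids
  curve <- data.table::data.table(x = x, alpha = 0.5 - 0.4 * exp(-3 * x))
  fit <- fit_asymptotic_alpha(curve)
  expect_equal(fit$method, "exponential")
  expect_equal(fit$alpha_asymptotic, 0.5 - 0.4 * exp(-3), tolerance = 1e-6)
  expect_equal(fit$a, 0.5, tolerance = 1e-5)
  expect_equal(fit$b, -0.4, tolerance = 1e-4)
  expect_equal(fit$c, 3, tolerance = 1e-4)
  # a constant curve still reports its level
  flat <- data.table::data.table(x = x, alpha = rep(0.2, 9))
  ffit <- fit_asymptotic_alpha(flat)
  expect_equal(ffit$alpha_asymptotic, 0.2, tolerance = 1e-3)
  expect_error(
    fit_asymptotic_alpha(data.table::data.table(x = x[1:3],
                                                alpha = c(1, 2, 3))),
    "4")
})

test_that("DoS matches its definition and exclusion rule", {
  tab <- data.frame(Dn = c(10, 2, 1, 0, 3),
                    Ds = c(10, 0, 3, 0, 1),
                    Pn = c(10, 0, 6, 5, 0),
                    Ps = c(10, 2, 2, 5, 0))
  d <- dos(tab)
  expect_equal(d[1], 0)
  expect_equal(d[2], 1)
  expect_equal(d[3], -0.5)
  expect_true(is.na(d[4]))  # no substituted site
  expect_true(is.na(d[5]))  # no polymorphic site
})

test_that("DoS and pooled alpha always agree in sign", {
  set.seed(20)
  for (r in 1:200) {
    Dn <- sample(1:20, 1); Ds <- sample(1:20, 1)
    Pn <- sample(1:20, 1); Ps <- sample(1:20, 1)
    a <- alpha_pooled(Dn, Ds, Pn, Ps)
    d <- dos(data.frame(Dn = Dn, Ds = Ds, Pn = Pn, Ps = Ps))
    expect_equal(sign(a), sign(d))
  }
})

test_that("DoS percentile gene sets use the 2.5/97.5 thresholds", {
  set.seed(22)
  dv <- stats::runif(1000, -1, 1)
  ids <- sprintf("g%04d", 1:1000)
  gs <- dos_gene_sets(dv, ids)
  expect_length(gs$lower, 25)
  expect_length(gs$upper, 25)
  expect_equal(gs$median, stats::median(dv))
  expect_true(all(dv[match(gs$lower, ids)] < gs$thresholds[1]))
  # degenerate and underpowered inputs
  expect_warning(out <- dos_gene_sets(rep(0.1, 10), sprintf("g%d", 1:10)),
                 "40")
  expect_length(out$lower, 0)
  gs2 <- dos_gene_sets(rep(0.5, 100), sprintf("g%d", 1:100))
  expect_length(gs2$lower, 0)
  expect_length(gs2$upper, 0)
})
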