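test_that("F_ST has the stated bounds and hand-computed value", {
  expect_equal(fst_from_counts(c(10, 0, 5, 0), c(10, 0, 5, 0)), 0)
  expect_equal(fst_from_counts(c(10, 0, 0, 0), c(0, 0, 0, 10)), 1)
  expect_equal(fst_from_counts(c(8, 0, 0, 2), c(2, 0, 0, 8)), 0.32444,
               tolerance = 1e-4)
  expect_true(is.na(fst_from_counts(c(10, 0, 0, 0), c(10, 0, 0, 0))))
  expect_error(fst_from_counts(c(0, 0, 0, 0), c(1, 0, 0, 0)), "depth")
  # symmetry over random pools
  set.seed(10)
  a <- random_counts(100)
  b <- random_counts(100)
  expect_equal(fst_from_counts(a, b), fst_from_counts(b, a))
})

test_that("gene-scope F_ST equals a window spanning the gene extent", {
  set.seed(11)
  a <- random_counts(400, depth = 50)
  b <- random_counts(400, depth = 50)
  genes <- data.frame(gene_id = c("g1", "g2"),
                      start = c(1, 201), end = c(200, 400))
  gf <- gene_fst(a, b, pos = 1:400, genes, min_depth = 10)
  for (k in 1:2) {
    sel <- genes$start[k]:genes$end[k]
    w <- window_fst(a[sel, ], b[sel, ], pos = sel, window_size = 2000000,
                    min_depth = 10, min_covered_fraction = 0)
    expect_equal(gf$fst[k], w$fst)
  }
})

test_that("Z_FST outliers flag the 0.5% tails", {
  set.seed(12)
  z <- zfst_outliers(stats::rnorm(1000))
  expect_equal(sum(z$outlier == "high"), 5)
  expect_equal(sum(z$outlier == "low"), 5)
  expect_equal(mean(z$z_fst), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z$z_fst), 1, tolerance = 1e-12)
  expect_error(zfst_outliers(rep(0.3, 500)), "variance")
  expect_warning(zfst_outliers(stats::rnorm(50)), "200")
})

test_that("Fisher tests and BH correction match their oracles", {
  f <- snp_fisher_bh(c(10, 0, 0, 0), c(0, 0, 0, 10))
  expect_equal(f$p, 2 / choose(20, 10))
  expect_equal(snp_fisher_bh(c(7, 0, 3, 0), c(7, 0, 3, 0))$p, 1)
  expect_equal(snp_fisher_bh(c(10, 0, 0, 0), c(10, 0, 0, 0))$p, 1)
  # BH hand example
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
})

test_that("candidate genes require all three selection criteria", {
  windows <- data.frame(start = c(1, 1001), end = c(1000, 2000),
                        outlier = c("high", "none"))
  genes <- data.frame(gene_id = c("gA", "gB", "gC"),
                      start = c(100, 600, 1100), end = c(500, 900, 1900))
  gene_tab <- data.table::data.table(
    gene_id = c("gA", "gB", "gC"),
    fst = c(0.9, 0.9, 0.1))
  # gA: outlier window + high gene fst + significant SNP -> candidate
  # gB: outlier window + high gene fst but no significant SNP -> no
  # gC: neither window nor gene criterion -> no
  res <- candidate_genes(genes, windows, gene_tab,
                         snp_pos = c(120, 1200), snp_sig = c(TRUE, TRUE),
                         upper_q = 0.25)
  expect_true(res[res$gene_id == "gA"]$candidate)
  expect_false(res[res$gene_id == "gB"]$candidate)
  expect_false(res[res$gene_id == "gC"]$candidate)
})

test_that("neighbor joining solves 3-taxon branch lengths exactly", {
  d <- matrix(c(0, 5, 9,
                5, 0, 10,
                9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  nwk <- nj_tree(d)
  tr <- ape::read.tree(text = nwk)
  # three-point formulas: x_a = (d_ab + d_ac - d_bc)/2 etc.
  want <- c(a = (5 + 9 - 10) / 2, b = (5 + 10 - 9) / 2,
            c = (9 + 10 - 5) / 2)
  got <- stats::setNames(
    tr$edge.length[match(seq_along(tr$tip.label), tr$edge[, 2])],
    tr$tip.label)
  expect_equal(got[names(want)], want)
  expect_error(nj_tree(d[1:2, 1:2]), "3 taxa")
  d2 <- d; d2[1, 2] <- 7
  expect_error(nj_tree(d2), "symmetric")
})

test_that("neighbor joining recovers additive 4-taxon trees exactly", {
  set.seed(15)
  for (r in 1:5) {
    tr <- ape::rtree(4)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.5, 2)
    d <- ape::cophenetic.phylo(tr)
    est <- ape::read.tree(text = nj_tree(d))
    # recovered tree reproduces all pairwise distances
    d2 <- ape::cophenetic.phylo(est)[rownames(d), colnames(d)]
    expect_equal(d2, d, tolerance = 1e-8)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(est))[1], 0)
  }
})

test_that("mean window F_ST increases with split time", {
  f <- fst_split_series()
  expect_true(all(diff(f) > 0))
})
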