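test_that("degeneracy classes match direct codon-table reasoning", {
  seqs <- c(chr1 = "GGAATGAAA")  # Gly, Met, Lys
  cds <- data.frame(chrom = "chr1", start = 1, end = 9, strand = "+",
                    gene_id = "g1")
  d <- classify_degeneracy(seqs, cds)
  expect_equal(d$class[d$pos == 2], "four_fold")   # GGN all glycine
  expect_equal(d$class[d$pos %in% 3:5], rep("zero_fold", 3))  # ATG unique
  expect_equal(d$class[d$pos == 8], "other")       # AAA: 2-fold third slot
})

test_that("degeneracy agrees with a mutate-and-translate oracle on random genes", {
  set.seed(3)
  bases <- c("A", "C", "G", "T")
  for (strand in c("+", "-")) {
    codons <- replicate(60, paste0(sample(bases, 3, TRUE), collapse = ""))
    codons <- codons[Biostrings::GENETIC_CODE[codons] != "*"]
    gene <- paste0(codons, collapse = "")
    gseq <- if (strand == "+") gene else
      paste0(rev(strsplit(chartr("ACGT", "TGCA", gene), "")[[1]]),
             collapse = "")
    seqs <- c(chr1 = gseq)
    cds <- data.frame(chrom = "chr1", start = 1, end = nchar(gene),
                      strand = strand, gene_id = "g1")
    d <- classify_degeneracy(seqs, cds)
    expect_equal(nrow(d), nchar(gene))
    for (k in seq_len(nrow(d))) {
      cd <- codons[d$codon_index[k]]
      expect_equal(d$class[k], degeneracy_oracle(cd, d$codon_slot[k]),
                   info = sprintf("%s codon %s slot %d", strand, cd,
                                  d$codon_slot[k]))
    }
  }
})

test_that("reverse-complementing genome and annotation preserves class counts", {
  set.seed(14)
  lay <- genome_layout(n_cds = 8, cds_length = 90, spacer_length = 20)
  ref <- codon_reference(lay)
  cds <- layout_cds_table(lay)
  d_fwd <- classify_degeneracy(c(chr1 = ref), cds)

  L <- nchar(ref)
  rc <- paste0(rev(strsplit(chartr("ACGT", "TGCA", ref), "")[[1]]),
               collapse = "")
  cds_rc <- data.frame(chrom = "chr1",
                       start = L - cds$end + 1, end = L - cds$start + 1,
                       strand = "-", gene_id = cds$gene_id)
  d_rev <- classify_degeneracy(c(chr1 = rc), cds_rc)
  expect_equal(table(d_fwd$class), table(d_rev$class))
})

test_that("major-allele calls use majority rule with conservative masking", {
  expect_equal(call_major_allele(c(10, 0, 2, 0)), "A")
  expect_equal(call_major_allele(c(0, 0, 0, 0)), "N")   # uncovered
  expect_equal(call_major_allele(c(4, 4, 0, 0)), "N")   # tie
  expect_equal(call_major_allele(c(5, 3, 1, 0)), "N")   # > 2 alleles
  m <- rbind(c(9, 1, 0, 0), c(0, 0, 3, 7))
  expect_equal(call_major_allele(m), c("A", "T"))
})

test_that("polarization applies the DAF, single-read and exclusion rules", {
  counts <- rbind(c(18, 0, 2, 0),   # polymorphic, derived G at 0.10
                  c(39, 0, 1, 0),   # single minor read: monomorphic
                  c(1, 0, 39, 0),   # divergent site (fixed)
                  c(2, 0, 38, 0),   # daf 0.95 boundary: still polymorphic
                  c(1, 0, 79, 0))   # daf > 0.95 would be fixed; here mono-rule
  pol <- polarize(counts, rep("A", 5), min_depth = 1, max_depth = 100)
  expect_equal(pol$status[1], "polymorphic")
  expect_equal(pol$daf[1], 0.10)
  expect_equal(pol$derived[1], "G")
  expect_equal(pol$status[2], "monomorphic")
  expect_equal(pol$status[3], "fixed")
  expect_equal(pol$daf[3], 0.975)
  expect_equal(pol$status[4], "polymorphic")  # 38/40 = 0.95 inside band
  expect_equal(pol$status[5], "fixed")

  # exclusions: outgroup N, cross-species triallelic, >2 alleles, coverage
  pol2 <- polarize(rbind(c(18, 0, 2, 0),
                         c(18, 0, 2, 0),
                         c(10, 8, 6, 0),
                         c(18, 0, 2, 0),
                         c(18, 0, 2, 0)),
                   c("N", "T", "A", "A", "A"),
                   min_depth = 10, max_depth = c(100, 100, 100, 15, 100))
  expect_equal(pol2$status[1:4], rep("excluded", 4))
  expect_equal(pol2$status[5], "polymorphic")

  # daf + ancestral frequency = 1 for biallelic sites
  anc <- 1 - pol$daf
  expect_equal(pol$daf + anc, rep(1, 5))
})

test_that("the posterior segregation filter keeps real SNPs and drops noise", {
  expect_true(segregation_filter(10, 40))
  expect_false(segregation_filter(0, 40))
  expect_error(segregation_filter(5, 40, threshold = 1), "threshold")
  expect_error(segregation_filter(5, 40, threshold = 0), "threshold")
  # posterior is the stated beta-binomial form
  post <- segregation_posterior(10, 40, error_rate = 0.01)
  num <- 1 / 41
  den <- num + stats::dbinom(10, 40, 0.01) + stats::dbinom(10, 40, 0.99)
  expect_equal(post, num / den)
  expect_gt(post, 0.9)
})

test_that("polarization recovers the true derived allele on clean deep pools", {
  fx <- clean_fixture()
  sync <- read_sync(fx$paths$sync, names(fx$sim$populations))
  og <- read_fasta(fx$paths$outgroup)[[1]]
  og_base <- substring(og, sync$pos, sync$pos)
  pol <- polarize(sync$counts[[1]], og_base, min_depth = 50, max_depth = 400)
  truth <- read.delim(fx$paths$truth_pop1)
  truth <- truth[truth$freq > 0.05 & truth$freq < 0.95, ]
  idx <- truth$pos + 1L
  called <- pol$derived[idx]
  ok <- !is.na(called) & called == truth$derived_base
  expect_gt(mean(ok), 0.99)
  # and sites well inside the band are called polymorphic
  mid <- truth$freq > 0.15 & truth$freq < 0.85
  expect_gt(mean(pol$status[idx][mid] == "polymorphic"), 0.95)
})
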