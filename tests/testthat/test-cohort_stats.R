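test_that("SV burden counts breakpoints on autosomes and X only", {
  auto <- mk_svs(p1 = (1:5) * 1e6, p2 = (1:5) * 1e6 + 1e5)
  expect_equal(sv_burden(auto), 10)
  tra_y <- sv_calls("chr1", 1e6, "+", "chrY", 2e6, "-", svtype = "TRA")
  expect_equal(sv_burden(tra_y), 1)
  expect_equal(sv_burden(auto[0, ]), 0)
})

test_that("TMB divides non-synonymous coding SNVs by coding megabases", {
  snvs <- mk_snvs((1:6) * 100)
  ann <- data.frame(
    key = snvs$key, gene = "G",
    consequence = c(rep("missense_variant", 5), "synonymous_variant"),
    impact = "MODERATE", deleterious = TRUE, stringsAsFactors = FALSE)
  expect_equal(tmb(snvs, ann, coding_mb = 2.5), 2.0)
  all_syn <- ann; all_syn$consequence <- "synonymous_variant"
  expect_equal(tmb(snvs, all_syn, coding_mb = 2.5), 0)
  expect_error(tmb(snvs, ann, coding_mb = 0), "territory")
})

test_that("coding territory merges overlapping exons", {
  m <- structure(list(
    genes = data.frame(gene = c("A", "B"), chrom = "chr1", strand = "+",
                       start = c(0, 5e5), end = c(1e6, 2e6),
                       stringsAsFactors = FALSE),
    exons = data.frame(gene = c("A", "A", "B"), chrom = "chr1",
                       start = c(0, 4e5, 5e5), end = c(2e5, 6e5, 7e5),
                       stringsAsFactors = FALSE)
  ), class = "gene_models")
  # union: [0,2e5) + [4e5,7e5) = 0.5 Mb (A's second exon overlaps B's)
  expect_equal(coding_territory_mb(m), 0.5)
})

test_that("Welch's t handles identical and degenerate samples", {
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(welch_t(c(5, 5), c(5, 5))$t, 0)
  expect_equal(welch_t(c(5, 5), c(5, 5))$p, 1)
  res <- welch_t(c(0, 0, 0, 0), c(10, 10, 10, 10.0001))
  expect_lt(res$p, 0.001)
  # agrees with the standard implementation as an oracle
  set.seed(3)
  a <- rnorm(10); b <- rnorm(12, 1)
  ref <- t.test(a, b)
  got <- welch_t(a, b)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)
  expect_error(welch_t(1, c(1, 2)), ">= 2")
})

test_that("chi-square on 2x2 reproduces the PTEN-loss comparison and is swap-invariant", {
  res <- chisq_2x2(12, 10, 11, 35)
  expect_equal(signif(res$p, 3), 0.0125)
  expect_equal(chisq_2x2(5, 5, 5, 5)$chi2, 0)
  expect_equal(chisq_2x2(5, 5, 5, 5)$p, 1)
  expect_lt(chisq_2x2(10, 0, 0, 10)$p, 0.001)
  # invariance under transposition and row/column swaps
  expect_equal(chisq_2x2(12, 10, 11, 35)$chi2, chisq_2x2(12, 11, 10, 35)$chi2)
  expect_equal(chisq_2x2(12, 10, 11, 35)$chi2, chisq_2x2(11, 35, 12, 10)$chi2)
  expect_equal(chisq_2x2(12, 10, 11, 35)$chi2, chisq_2x2(10, 12, 35, 11)$chi2)
  expect_error(chisq_2x2(0, 0, 3, 4), "margin")
})

test_that("Fisher exact matches full hypergeometric enumeration", {
  expect_equal(fisher_2x2(0, 5, 5, 0), 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_2x2(1, 1, 1, 1), 1.0)
  # all tables with total n <= 30 against the enumeration oracle
  for (n in c(8, 15, 30)) {
    for (a in 0:min(6, n)) for (b in 0:min(4, n - a)) {
      for (c in 0:min(4, n - a - b)) {
        d <- n - a - b - c
        for (s in c("two.sided", "greater", "less")) {
          expect_equal(fisher_2x2(a, b, c, d, sided = s),
                       oracle_fisher(a, b, c, d, sided = s),
                       tolerance = 1e-12)
        }
      }
    }
  }
  # one-sided enrichment p is monotone decreasing in a at fixed margins
  ps <- vapply(0:6, function(a) fisher_2x2(a, 6 - a, 6 - a, 18 + a,
                                           sided = "greater"), 0)
  expect_true(all(diff(ps) < 0))
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(2)
  p <- runif(40)
  q <- bh_adjust(p)
  expect_equal(q, p.adjust(p, "BH")) # reference implementation as oracle
  expect_true(all(q >= p))
  # order preserving
  expect_equal(order(q[order(p)]), seq_along(p))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("cross-cohort enrichment applies the sparse-count filter and finds planted signal", {
  genes <- paste0("g", 1:30)
  mk_matrix <- function(freqs, n) {
    m <- matrix(0L, length(genes), n, dimnames = list(genes, NULL))
    for (i in seq_along(genes)) m[i, seq_len(round(freqs[i] * n))] <- 1L
    m
  }
  # a gene altered in 9 reference cases is not tested
  a <- mk_matrix(rep(0.5, 30), 20)
  b <- mk_matrix(rep(9 / 46, 30), 46)
  expect_equal(nrow(cross_cohort_enrichment(a, b, min_cases = 10)), 0)
  # identical cohorts -> all p = 1
  same <- mk_matrix(rep(0.5, 30), 40)
  res <- cross_cohort_enrichment(same, same)
  expect_true(all(abs(res$p - 1) < 1e-9))
  # planted 10-fold difference at n = 50 per cohort reaches q < 0.05:
  # g1 altered in 4/50 of cohort A vs 40/50 of cohort B
  pa <- mk_matrix(c(0.08, rep(0.25, 29)), 50)
  pb <- mk_matrix(c(0.80, rep(0.25, 29)), 50)
  res2 <- cross_cohort_enrichment(pa, pb)
  expect_lt(res2$q[res2$gene == "g1"], 0.05)
  expect_equal(res2$direction[res2$gene == "g1"], "depleted_in_a")
})
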