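annotated_cohort_fixture <- function() {
  data.frame(
    sample_id = c("s1", "s1", "s1", "s2", "s2", "s3"),
    ref = "C", alt = "T",
    gene_ids = c("APC", "APC", "XKR4", "APC", "TP53", "TP53"),
    region_class = c("CDS", "CDS", "UTR3", "CDS", "CDS", "CDS"),
    non_silent = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

test_that("mutation matrices collapse duplicates and respect channels", {
  ann <- annotated_cohort_fixture()
  mat <- build_mutation_matrix(ann, "coding_nonsilent")
  expect_equal(mat["APC", "s1"], 1L)   # two APC hits collapse to one
  expect_equal(sum(mat["APC", ]), 2L)
  expect_false("XKR4" %in% rownames(mat))  # UTR3 not in coding channel
  utr <- build_mutation_matrix(ann, "UTR3")
  expect_equal(rownames(utr), "XKR4")
  expect_error(build_mutation_matrix(ann, "promoter"), "unknown channel")
  empty <- build_mutation_matrix(ann[0, ], "coding_nonsilent")
  expect_equal(dim(empty), c(0L, 0L))
})

test_that("recurrent genes are cut, sorted and tie-broken alphabetically", {
  mat <- matrix(c(1, 1, 1, 0,
                  1, 1, 0, 0,
                  0, 1, 1, 0,
                  1, 0, 0, 0), 4, 4, byrow = TRUE,
                dimnames = list(c("B", "A", "C", "D"), paste0("s", 1:4)))
  rec <- recurrent_genes(mat, min_samples = 2)
  expect_equal(rec$gene, c("B", "A", "C"))
  expect_equal(rec$n_samples, c(3L, 2L, 2L))
  all_g <- recurrent_genes(mat, min_samples = 1)
  expect_equal(nrow(all_g), 4)
})

test_that("mutual exclusivity applies the at-most-one-overlap rule", {
  mat <- matrix(0L, 2, 12, dimnames = list(c("A", "B"), paste0("s", 1:12)))
  mat["A", 1:3] <- 1L
  mat["B", 4:6] <- 1L
  r <- mutual_exclusivity(mat, "A", "B")
  expect_equal(r$overlap, 0)
  expect_true(r$exclusive)

  mat["A", ] <- 0L; mat["B", ] <- 0L
  mat["A", 1:2] <- 1L; mat["B", 2:3] <- 1L
  r2 <- mutual_exclusivity(mat, "A", "B")
  expect_equal(r2$overlap, 1)
  expect_true(r2$exclusive)

  mat["A", ] <- 0L; mat["B", ] <- 0L
  mat["A", 1:3] <- 1L; mat["B", c(1, 2, 4)] <- 1L
  r3 <- mutual_exclusivity(mat, "A", "B")
  expect_equal(r3$overlap, 2)
  expect_false(r3$exclusive)

  # symmetric in the gene pair
  r4 <- mutual_exclusivity(mat, "B", "A")
  expect_equal(r4$overlap, r3$overlap)
  expect_equal(r4$fisher_p, r3$fisher_p)
  expect_error(mutual_exclusivity(mat, "A", "Z"), "not in matrix")
})

test_that("Fisher exact p matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2)), 0.1)
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2)), 1.0)
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2)), 1 / 3)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 5), 2)), 1)  # zero margin

  # independent cross-check on random tables with n <= 40
  set.seed(8)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 4), 2)
    if (sum(tab) > 40 || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      next
    expect_equal(fisher_exact_2x2(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("chi-square test reproduces closed-form values", {
  same <- matrix(c(5, 5, 7, 7), 2, byrow = TRUE)
  r <- chi2_test_2x2(matrix(c(5, 7, 5, 7), 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  sep <- chi2_test_2x2(matrix(c(10, 0, 0, 10), 2))
  expect_equal(sep$statistic, 20)
  expect_equal(sep$p, stats::pchisq(20, 1, lower.tail = FALSE))
  expect_lt(abs(sep$p - 7.7e-6), 1e-6)

  # a statistic of 4.0 corresponds to p 0.0455
  expect_equal(stats::pchisq(4, 1, lower.tail = FALSE), 0.0455,
               tolerance = 1e-3)
  tab <- matrix(c(4, 0, 0, 4), 2)
  got <- chi2_test_2x2(tab)
  # reference value from the small-count test, approximation warning aside
  ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  expect_equal(got$p, ref, tolerance = 1e-12)
  expect_error(chi2_test_2x2(matrix(c(0, 0, 1, 1), 2)), "expected")
})

test_that("BH adjustment equals the step-up formula", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    q <- bh_adjust(p)
    expect_equal(q, brute_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
})

test_that("hypergeometric enrichment is the upper-tail draw probability", {
  universe <- paste0("g", 1:10)
  gene_set <- universe[1:5]
  expect_equal(hypergeometric_enrichment(universe[1:5], gene_set, universe),
               1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(hypergeometric_enrichment(universe, gene_set, universe), 1)
  # empty intersection: observing >= 0 successes is certain
  disjoint <- hypergeometric_enrichment(universe[6:7], gene_set, universe)
  expect_equal(disjoint, 1)
  expect_error(hypergeometric_enrichment("zzz", gene_set, universe),
               "subsets")
})
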