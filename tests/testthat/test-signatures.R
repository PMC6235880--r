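test_that("catalog construction collapses to the pyrimidine convention", {
  snvs <- data.frame(ref = c("C", "G"), alt = c("A", "T"),
                     context = c("ACA", "TGT"), stringsAsFactors = FALSE)
  cat96 <- build_catalog(snvs)
  expect_equal(unname(unclass(cat96)["A[C>A]A"]), 2)
  expect_equal(catalog_total(cat96), 2)

  empty <- build_catalog(snvs[0, ])
  expect_equal(catalog_total(empty), 0)

  withN <- data.frame(ref = "C", alt = "A", context = "NCA")
  skipped <- build_catalog(withN)
  expect_equal(catalog_total(skipped), 0)
  expect_equal(attr(skipped, "skipped"), 1)
})

test_that("NNLS recovers exact mixtures and matches an independent solver", {
  W <- test_signatures(3)
  C <- as_catalog96(setNames(as.vector(W$W %*% c(30, 70, 0)),
                             context_labels_96()))
  fit <- nnls_decompose(C, W)
  expect_equal(unname(fit$exposure), c(30, 70, 0), tolerance = 1e-9)
  expect_equal(unname(fit$normalized), c(0.3, 0.7, 0), tolerance = 1e-9)

  C1 <- as_catalog96(setNames(100 * W$W[, 1], context_labels_96()))
  expect_equal(unname(nnls_decompose(C1, W)$exposure), c(100, 0, 0),
               tolerance = 1e-9)
  expect_error(nnls_decompose(as_catalog96(numeric()), W), "empty")

  skip_if_not_installed("pracma")
  W5 <- test_signatures(5, seed = 13)
  set.seed(4)
  for (i in 1:50) {
    C <- as.numeric(rmultinom(1, 3000, as.vector(W5$W %*% runif(5))))
    mine <- nnls_fit(W5$W, C)$x
    oracle <- pracma::lsqnonneg(W5$W, C)$x
    expect_lt(max(abs(mine - oracle)), 1e-6)
  }
})

test_that("NNLS solutions are optimal under coordinate perturbation and scale-equivariant", {
  W <- test_signatures(4, seed = 3)
  set.seed(9)
  for (i in 1:10) {
    C <- as.numeric(rmultinom(1, 2000, as.vector(W$W %*% runif(4))))
    fit <- nnls_fit(W$W, C)
    res <- function(x) sqrt(sum((W$W %*% x - C)^2))
    for (j in 1:4) for (eps in c(-0.5, 0.5)) {
      x2 <- fit$x
      x2[j] <- max(0, x2[j] + eps)
      expect_gte(res(x2), fit$residual - 1e-8)
    }
    cat2 <- as_catalog96(setNames(3 * C, context_labels_96()))
    fit2 <- nnls_decompose(cat2, W)
    expect_equal(fit2$exposure, 3 * setNames(fit$x, W$signature_ids),
                 tolerance = 1e-6)
    expect_equal(fit2$normalized,
                 setNames(fit$x / sum(fit$x), W$signature_ids),
                 tolerance = 1e-6)
  }
})

test_that("signature cutoffs iterate the stated removal rule", {
  W <- test_signatures(2, seed = 5)
  C <- as_catalog96(setNames(as.vector(W$W %*% c(970, 30)),
                             context_labels_96()))
  # all cutoffs zero: identity with the plain fit
  f0 <- apply_signature_cutoffs(C, W, 0)
  expect_equal(f0$exposure, nnls_decompose(C, W)$exposure)
  # (0.97, 0.03) with cutoff 0.05 drops signature 2, refits on 1 alone
  f <- apply_signature_cutoffs(C, W, 0.05)
  expect_equal(unname(f$exposure[2]), 0)
  expect_gt(f$exposure[1], 0)
  refit <- nnls_fit(W$W[, 1, drop = FALSE], as.numeric(C))
  expect_equal(unname(f$exposure[1]), refit$x, tolerance = 1e-9)

  # independent re-execution of the iterative rule on random catalogs
  W5 <- test_signatures(5, seed = 13)
  set.seed(10)
  for (i in 1:10) {
    e <- rgamma(5, 0.5); e <- e / sum(e)
    C <- generate_catalog_from_exposures(W5, e, 3000)
    got <- apply_signature_cutoffs(C, W5, 0.1)
    active <- W5$signature_ids
    repeat {
      x <- nnls_fit(W5$W[, active, drop = FALSE], as.numeric(C))$x
      norm <- x / sum(x)
      below <- active[norm < 0.1]
      if (!length(below)) break
      active <- setdiff(active, below)
    }
    expect_setequal(got$signature_ids[got$exposure > 0], active)
    expect_true(all(got$normalized[got$exposure > 0] >= 0.1))
  }
})

test_that("raising a cutoff never adds a surviving signature", {
  W <- test_signatures(4, seed = 3)
  set.seed(2)
  C <- generate_catalog_from_exposures(W, c(0.5, 0.3, 0.15, 0.05), 5000)
  prev <- NULL
  for (cut in c(0, 0.02, 0.08, 0.2, 0.4)) {
    f <- suppressWarnings(apply_signature_cutoffs(C, W, cut))
    surv <- f$signature_ids[f$exposure > 0]
    if (!is.null(prev)) expect_true(all(surv %in% prev))
    prev <- surv
  }
})

test_that("cohort-level detection finds the generating signatures", {
  W <- test_signatures(5, seed = 13)
  set.seed(6)
  catalogs <- lapply(1:6, function(i)
    generate_catalog_from_exposures(W, c(0.6, 0, 0, 0, 0.4), 5000))
  active <- cohort_signature_detection(catalogs, W, 0.01)
  expect_setequal(active, c("S1", "S5"))

  one <- cohort_signature_detection(catalogs[1], W, 0.06)
  per_sample <- apply_signature_cutoffs(catalogs[[1]], W, 0.06)
  expect_setequal(one, per_sample$signature_ids[per_sample$exposure > 0])

  expect_error(cohort_signature_detection(list(), W), "empty cohort")
  expect_error(
    suppressWarnings(cohort_signature_detection(catalogs, W, 1.0)),
    "no signature")
})

test_that("exposure recovery from simulated catalogs reaches cosine 0.95", {
  W <- test_signatures(6, seed = 21)
  set.seed(3)
  for (i in 1:5) {
    e <- rgamma(6, 0.7); e <- e / sum(e)
    C <- generate_catalog_from_exposures(W, e, 10000)
    fit <- nnls_decompose(C, W)
    cosine <- sum(e * fit$normalized) /
      sqrt(sum(e^2) * sum(fit$normalized^2))
    expect_gte(cosine, 0.95)
  }
})

test_that("strata comparison uses the exact paired signed-rank distribution", {
  sigs <- paste0("S", 1:3)
  pat <- paste0("P", 1:8)
  a <- matrix(0.3, 8, 3, dimnames = list(pat, sigs))
  res_same <- compare_strata_exposures(list(shared = a, met_private = a))
  expect_true(all(res_same$p == 1))

  set.seed(7)
  b <- a
  b[, "S2"] <- a[, "S2"] + runif(8, 0.01, 0.1)  # S2 higher in one stratum
  res <- compare_strata_exposures(list(shared = a, met_private = b))
  row <- res[res$signature == "S2", ]
  d <- a[, "S2"] - b[, "S2"]
  expect_equal(row$p, brute_signed_rank_p(d), tolerance = 1e-9)
  expect_equal(row$p, 2 / 2^8, tolerance = 1e-9)
  expect_lt(row$median_diff, 0)
  expect_error(compare_strata_exposures(list(shared = a[1:2, ],
                                             met_private = b[1:2, ])),
               "at least 3")
})

test_that("exposure clustering matches a naive complete-linkage oracle", {
  m <- matrix(c(0.2, 0.8, 0.2, 0.8, 0.5, 0.5), ncol = 2, byrow = TRUE)
  res <- cluster_exposures(m)
  expect_equal(res$tree$height[1], 0)  # identical rows merge first
  merged_first <- sort(res$tree$merge[1, ])
  expect_equal(merged_first, c(-2, -1))

  set.seed(12)
  rnd <- matrix(runif(40), 8, 5)
  hc <- cluster_exposures(rnd)
  expect_equal(sort(hc$tree$height),
               brute_complete_linkage_heights(rnd), tolerance = 1e-12)
  expect_error(cluster_exposures(rnd[1, , drop = FALSE]), "at least 2")
})

test_that("group association uses the exact rank-sum distribution", {
  m <- matrix(c(1:4, 11:14), ncol = 1,
              dimnames = list(NULL, "S1"))
  g <- rep(c(TRUE, FALSE), each = 4)
  res <- associate_exposure_with_group(m, g)
  expect_equal(res$p, 2 / choose(8, 4), tolerance = 1e-9)

  same <- matrix(rep(1:4, 2), ncol = 1, dimnames = list(NULL, "S1"))
  expect_equal(associate_exposure_with_group(same, g)$p, 1)

  tiny <- matrix(c(1, 2), ncol = 1, dimnames = list(NULL, "S1"))
  expect_equal(associate_exposure_with_group(tiny, c(TRUE, FALSE))$p, 1)
  expect_error(associate_exposure_with_group(m, rep(TRUE, 8)),
               "two non-empty")
})
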