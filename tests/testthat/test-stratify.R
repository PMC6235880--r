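test_that("expected read support and the Poisson support model evaluate exactly", {
  expect_equal(expected_read_support(0.475, 36, 3), 5.7)
  expect_equal(expected_read_support(1.0, 30, 2), 15.0)
  expect_equal(expected_read_support(0.5, 40, 4), 5.0)
  expect_error(expected_read_support(0, 36, 3), "positive")

  expect_equal(poisson_support_probability(0, 1.0), exp(-1))
  expect_equal(poisson_support_probability(2, 5.7),
               exp(-5.7) * 5.7^2 / 2, tolerance = 1e-12)
  expect_equal(poisson_support_probability(2, 5.7), 0.0544,
               tolerance = 1e-3)
  expect_equal(poisson_support_probability(2, 2.0), 0.2707,
               tolerance = 2e-4)
  expect_error(poisson_support_probability(-1, 2), "non-negative")
})

test_that("minimum alt reads above a MAF threshold matches exhaustive search", {
  expect_equal(min_alt_reads_for_maf(36, 0.05), 2L)
  # independent oracle: scan read counts upward
  scan_min <- function(cov, t) {
    r <- 0L
    while (r / cov <= t) r <- r + 1L
    r
  }
  for (case in list(c(100, 0.05), c(20, 0.5), c(36, 0.05), c(77, 0.13))) {
    expect_equal(min_alt_reads_for_maf(case[1], case[2]),
                 scan_min(case[1], case[2]))
  }
})

test_that("cross-rescue applies the MAF, read-floor and germline-ratio rules", {
  calls <- data.frame(
    chrom = "1", pos = c(100, 200, 300),
    ref = "C", alt = "T",
    tumor_ref = 20L, tumor_alt = 10L, tumor_somatic = TRUE,
    met_ref = c(36L, 48L, 36L), met_alt = c(4L, 2L, 4L),
    met_somatic = FALSE,
    normal_ref = c(49L, 50L, 47L), normal_alt = c(1L, 0L, 3L),
    stringsAsFactors = FALSE)
  trio <- manual_trio(calls)
  # met MAF 0.10 vs control 0.02: rescued
  expect_equal(rescue_in_pair("1:100:C:T", trio),
               c(present_tumor = TRUE, present_met = TRUE))
  # met MAF 0.04: below the 5% threshold
  expect_equal(rescue_in_pair("1:200:C:T", trio),
               c(present_tumor = TRUE, present_met = FALSE))
  # met MAF 0.10 < 2 x control MAF 0.06: not rescued
  expect_equal(rescue_in_pair("1:300:C:T", trio),
               c(present_tumor = TRUE, present_met = FALSE))
  expect_error(rescue_in_pair("1:999:C:T", trio), "not found")
})

test_that("stratum assignment is the presence-pair mapping", {
  expect_equal(assign_stratum(TRUE, TRUE), "shared")
  expect_equal(assign_stratum(TRUE, FALSE), "tumor_private")
  expect_equal(assign_stratum(FALSE, TRUE), "met_private")
  expect_error(assign_stratum(FALSE, FALSE), "neither")
})

test_that("stratification recovers truth on synthetic trios (recall >= 0.95)", {
  W <- test_signatures(3)
  cfg <- trio_config(n_snvs = 5000, purity_tumor = 0.35, purity_met = 0.5,
                     ploidy_tumor = 3, ploidy_met = 2,
                     contamination_fraction = 0, n_germline = 0, seed = 11)
  sim <- generate_trio(cfg, W)
  st <- stratify_trio(sim$trio)
  truth_lab <- truth_as_stratum(sim$truth)
  names(truth_lab) <- variant_keys(sim$truth)
  got <- st$calls$stratum
  names(got) <- variant_keys(st$calls)
  common <- intersect(names(got), names(truth_lab))
  for (s in c("shared", "tumor_private", "met_private")) {
    keys <- common[truth_lab[common] == s]
    expect_gte(mean(got[keys] == s), 0.95)
  }
  expect_equal(sum(st$fractions), 1)
})

test_that("swapping tumor and metastasis swaps the private fractions exactly", {
  W <- test_signatures(3)
  cfg <- trio_config(n_snvs = 3000, purity_tumor = 0.4, purity_met = 0.7,
                     ploidy_tumor = 2, ploidy_met = 3,
                     contamination_fraction = 0, n_germline = 0, seed = 3)
  sim <- generate_trio(cfg, W)
  st <- stratify_trio(sim$trio)

  sw <- sim$trio
  calls <- sw$calls
  swap_cols <- function(df, a, b) {
    tmp <- df[[a]]; df[[a]] <- df[[b]]; df[[b]] <- tmp; df
  }
  for (p in list(c("tumor_ref", "met_ref"), c("tumor_alt", "met_alt"),
                 c("tumor_somatic", "met_somatic")))
    calls <- swap_cols(calls, p[1], p[2])
  sw$calls <- calls
  tmp <- sw$purity_tumor; sw$purity_tumor <- sw$purity_met
  sw$purity_met <- tmp
  tmp <- sw$ploidy_tumor; sw$ploidy_tumor <- sw$ploidy_met
  sw$ploidy_met <- tmp
  st_sw <- stratify_trio(sw)
  expect_equal(unname(st_sw$fractions["shared"]),
               unname(st$fractions["shared"]))
  expect_equal(unname(st_sw$fractions["tumor_private"]),
               unname(st$fractions["met_private"]))
  expect_equal(unname(st_sw$fractions["met_private"]),
               unname(st$fractions["tumor_private"]))
})

test_that("raising the MAF threshold never increases the shared fraction", {
  W <- test_signatures(3)
  sim <- generate_trio(trio_config(n_snvs = 4000, contamination_fraction = 0,
                                   n_germline = 0, seed = 8), W)
  shared <- vapply(c(0.02, 0.05, 0.10, 0.20, 0.35), function(t)
    stratify_trio(sim$trio, maf_threshold = t)$fractions["shared"],
    numeric(1))
  expect_true(all(diff(shared) <= 1e-12))
})

test_that("rescue compensates for halved metastasis depth", {
  W <- test_signatures(3)
  cfg <- trio_config(n_snvs = 8000, purity_tumor = 0.6, purity_met = 0.6,
                     contamination_fraction = 0, n_germline = 0, seed = 21)
  sim <- generate_trio(cfg, W)
  st_full <- stratify_trio(sim$trio)

  thin <- sim$trio
  set.seed(99)
  thin$calls$met_alt <- rbinom(nrow(thin$calls), thin$calls$met_alt, 0.5)
  thin$calls$met_ref <- rbinom(nrow(thin$calls), thin$calls$met_ref, 0.5)
  thin$calls$met_somatic <- thin$calls$met_somatic &
    thin$calls$met_alt >= 2
  st_half <- stratify_trio(thin)
  expect_lt(abs(st_half$fractions["shared"] - st_full$fractions["shared"]),
            0.03)
})

test_that("mutation rate per Mb reproduces the printed cohort value", {
  expect_equal(mutation_rate_per_mb(17189, 2.8e9), 6.1)
  expect_equal(mutation_rate_per_mb(0, 2.8e9), 0.0)
  expect_equal(mutation_rate_per_mb(2800, 2.8e9), 1.0)
  expect_error(mutation_rate_per_mb(10, 0))
})
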