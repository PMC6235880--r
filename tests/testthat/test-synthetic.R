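test_that("catalog generation follows the signature mixture", {
  W <- test_signatures(3)
  zero <- generate_catalog_from_exposures(W, c(1, 0, 0), 0, seed = 1)
  expect_equal(catalog_total(zero), 0)

  # law of large numbers: single-signature draw approaches its profile
  big <- generate_catalog_from_exposures(W, c(1, 0, 0), 1e6, seed = 2)
  freq <- as.numeric(big) / catalog_total(big)
  expect_lt(max(abs(freq - W$W[, 1])), 0.01)

  a <- generate_catalog_from_exposures(W, c(0.2, 0.3, 0.5), 500, seed = 3)
  b <- generate_catalog_from_exposures(W, c(0.2, 0.3, 0.5), 500, seed = 3)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_error(generate_catalog_from_exposures(W, c(-0.1, 0.6, 0.5), 10),
               "negative")
})

test_that("read-count simulation matches its binomial-Poisson model", {
  rc0 <- simulate_read_counts(0, 36, n = 200, seed = 1)
  expect_true(all(rc0$alt_count == 0))
  rc1 <- simulate_read_counts(1, 36, n = 200, seed = 1)
  expect_true(all(rc1$alt_count == rc1$depth))
  expect_true(all(rc1$depth >= 1))

  rc <- simulate_read_counts(0.25, 36, n = 1e5, seed = 2)
  expect_lt(abs(mean(rc$alt_count / rc$depth) - 0.25), 0.005)
})

test_that("expected clonal VAF is exact for a pure diploid", {
  expect_equal(expected_vaf(1, 2, 1), 0.5)
  expect_equal(expected_vaf(0.475, 3), 0.475 / (0.475 * 3 + 2 * 0.525))
})

test_that("trio generation conserves truth labels and fractions", {
  W <- test_signatures(3)
  cfg <- trio_config(n_snvs = 10000, contamination_fraction = 0,
                     n_germline = 0, seed = 5)
  sim <- generate_trio(cfg, W)
  expect_equal(nrow(sim$truth), 10000)
  expect_true(all(sim$truth$stratum %in%
                    c("truncal", "tumor_private", "met_private")))
  frac <- table(sim$truth$stratum)[c("truncal", "tumor_private",
                                     "met_private")] / 10000
  expect_lt(max(abs(frac - cfg$fractions)), 0.02)

  # determinism: identical seeds give identical datasets
  sim2 <- generate_trio(cfg, W)
  expect_identical(sim$trio$calls, sim2$trio$calls)
  expect_identical(sim$truth, sim2$truth)

  # degenerate fraction settings
  all_shared <- generate_trio(
    trio_config(n_snvs = 1000, fractions = c(1, 0, 0),
                purity_tumor = 0.9, purity_met = 0.9,
                contamination_fraction = 0, n_germline = 0, seed = 1), W)
  st <- stratify_trio(all_shared$trio)
  expect_equal(unname(st$fractions["shared"]), 1.0)

  tumor_only <- generate_trio(
    trio_config(n_snvs = 500, fractions = c(0, 1, 0),
                contamination_fraction = 0, n_germline = 0, seed = 1), W)
  expect_true(all(tumor_only$trio$calls$met_alt == 0))
  expect_false(any(tumor_only$trio$calls$met_somatic))

  expect_error(trio_config(fractions = c(0.5, 0.2, 0.2)), "summing to 1")
})

test_that("contaminated truncal variants leak into the normal and lose their call", {
  W <- test_signatures(3)
  cfg <- trio_config(n_snvs = 4000, contamination_fraction = 0.1,
                     n_germline = 0, seed = 9)
  sim <- generate_trio(cfg, W)
  cont <- sim$truth$contaminated
  expect_equal(sum(cont),
               floor(0.1 * sum(sim$truth$stratum == "truncal")))
  calls <- sim$trio$calls
  expect_true(all(calls$germline[cont]))
  expect_false(any(calls$tumor_somatic[cont] | calls$met_somatic[cont]))
  expect_gt(mean(calls$normal_alt[cont] > 0), 0.8)
  expect_true(all(calls$normal_alt[!cont & !calls$germline] == 0))
})

test_that("kataegis injection creates detectable clusters and records truth", {
  W <- test_signatures(3)
  cfg <- trio_config(n_snvs = 300, purity_tumor = 0.9, purity_met = 0.9,
                     contamination_fraction = 0, n_germline = 0, seed = 2)
  sim <- generate_trio(cfg, W)
  expect_identical(inject_kataegis(sim, 0), sim)

  inj <- inject_kataegis(sim, n_loci = 2, cluster_size = 5, span = 9000,
                         seed = 4)
  expect_equal(sum(!is.na(inj$truth$kataegis_locus)), 10)
  snv <- inj$trio$calls[inj$trio$calls$tumor_somatic, c("chrom", "pos")]
  loci <- detect_kataegis(snv)
  expect_gte(nrow(loci), 2)

  # below-threshold clusters stay invisible at default parameters
  small <- inject_kataegis(sim, n_loci = 1, cluster_size = 4, span = 9000,
                           seed = 4)
  snv_s <- small$trio$calls[small$trio$calls$tumor_somatic,
                            c("chrom", "pos")]
  expect_equal(nrow(detect_kataegis(snv_s)), 0)

  expect_error(inject_kataegis(sim, 1, cluster_size = 5, span = 3),
               "span too small")
})

test_that("the cohort preset draws within its documented ranges", {
  cfgs <- crc_cohort_configs(n_patients = 12, seed = 3)
  expect_length(cfgs, 12)
  for (cfg in cfgs) {
    expect_true(cfg$n_snvs >= 5000 && cfg$n_snvs <= 17000)
    expect_true(cfg$purity_tumor >= 0.35 && cfg$purity_tumor <= 0.85)
    expect_true(cfg$ploidy_tumor %in% 2:3)
    expect_equal(cfg$mean_coverage, 36)
    expect_equal(unname(cfg$fractions), c(0.65, 0.15, 0.20))
    for (e in cfg$exposures) expect_equal(sum(e), 1)
  }
})
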