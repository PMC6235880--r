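#' Trio simulation configuration
#'
#' Bundles every knob of the synthetic trio generator. Fractions are the
#' truth proportions of truncal (shared), tumor-private and
#' metastasis-private somatic SNVs; purity/ploidy parameterize the expected
#' variant allele fraction of a single-copy clonal variant,
#' purity * mult / (purity * CN + 2 * (1 - purity)) with CN taken as the
#' sample ploidy and multiplicity 1.
#'
#' @param patient_id patient label.
#' @param n_snvs total somatic SNVs to simulate.
#' @param fractions length-3 numeric (truncal, tumor_private, met_private),
#'   must sum to 1.
#' @param purity_tumor,purity_met tumor cell content in (0, 1].
#' @param ploidy_tumor,ploidy_met sample base ploidy (> 0).
#' @param mean_coverage mean sequencing depth (> 0).
#' @param exposures named list with elements truncal, tumor_private,
#'   met_private, each a non-negative vector over signature IDs summing
#'   to 1, or NULL to draw sparse random exposures at generation time.
#' @param contamination_fraction fraction of truncal variants whose reads
#'   leak into the matched normal (tumor-in-normal), in [0, 0.5).
#' @param n_germline number of germline heterozygous BAF positions carried
#'   along for tumor-in-normal rescue testing.
#' @param common_fraction fraction of germline positions marked as known
#'   common variants (filtered before clustering).
#' @param genome genome model data.frame (chrom, length).
#' @param seed default RNG seed used by \code{\link{generate_trio}}.
#' @return a \code{trio_config} list.
#' @export
trio_config <- function(patient_id = "P1", n_snvs = 10000,
                        fractions = c(truncal = 0.65, tumor_private = 0.15,
                                      met_private = 0.20),
                        purity_tumor = 0.6, purity_met = 0.6,
                        ploidy_tumor = 2, ploidy_met = 2,
                        mean_coverage = 36, exposures = NULL,
                        contamination_fraction = 0,
                        n_germline = 2000, common_fraction = 0.8,
                        genome = default_genome_model(), seed = 1) {
  fractions <- unlist(fractions)
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be 3 values summing to 1")
  if (any(fractions < 0)) stop("negative stratum fraction")
  names(fractions) <- c("truncal", "tumor_private", "met_private")
  stopifnot(purity_tumor > 0, purity_tumor <= 1, purity_met > 0,
            purity_met <= 1, ploidy_tumor > 0, ploidy_met > 0,
            mean_coverage > 0, n_snvs >= 0,
            contamination_fraction >= 0, contamination_fraction < 0.5)
  if (!is.null(exposures)) {
    stopifnot(all(c("truncal", "tumor_private", "met_private")
                  %in% names(exposures)))
    for (e in exposures) {
      if (any(e < 0)) stop("negative exposure in config")
      if (abs(sum(e) - 1) > 1e-9) stop("exposures must sum to 1")
    }
  }
  structure(list(patient_id = patient_id, n_snvs = n_snvs,
                 fractions = fractions, purity_tumor = purity_tumor,
                 purity_met = purity_met, ploidy_tumor = ploidy_tumor,
                 ploidy_met = ploidy_met, mean_coverage = mean_coverage,
                 exposures = exposures,
                 contamination_fraction = contamination_fraction,
                 n_germline = n_germline, common_fraction = common_fraction,
                 genome = genome, seed = seed),
            class = "trio_config")
}

#' The colorectal trio cohort preset
#'
#' Draws per-patient configurations emulating the published colorectal
#' trio cohort: 12 patients; stratum fractions (0.65, 0.15, 0.20) (the
#' reported 65/15/19% rounded so the fractions sum to 1); SNV load uniform
#' in [5000, 17000] unless fixed; purity uniform in [0.35, 0.85]; ploidy 2
#' or 3; coverage 36; tumor-in-normal contamination 5% of truncal variants.
#'
#' @param n_patients number of trios (default 12).
#' @param n_snvs fixed SNV count per patient, or NULL to draw uniformly
#'   from [5000, 17000].
#' @param signature_ids signature IDs used when drawing per-stratum
#'   exposures (3 active signatures per stratum, Dirichlet weights).
#' @param contamination_fraction tumor-in-normal contamination level.
#' @param seed RNG seed for the preset draws; patient i generates with
#'   seed + i.
#' @return list of \code{trio_config} objects.
#' @export
crc_cohort_configs <- function(n_patients = 12, n_snvs = NULL,
                                 signature_ids = paste0("S", 1:12),
                                 contamination_fraction = 0.05, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_patients), function(i) {
    n <- if (is.null(n_snvs)) round(stats::runif(1, 5000, 17000)) else n_snvs
    exposures <- lapply(1:3, function(j) {
      e <- stats::setNames(numeric(length(signature_ids)), signature_ids)
      active <- sample(signature_ids, 3)
      w <- stats::rgamma(3, 1)
      e[active] <- w / sum(w)
      e
    })
    names(exposures) <- c("truncal", "tumor_private", "met_private")
    trio_config(
      patient_id = sprintf("SIM-%03d", i), n_snvs = n,
      purity_tumor = stats::runif(1, 0.35, 0.85),
      purity_met = stats::runif(1, 0.35, 0.85),
      ploidy_tumor = sample(2:3, 1), ploidy_met = sample(2:3, 1),
      mean_coverage = 36, exposures = exposures,
      contamination_fraction = contamination_fraction,
      seed = seed + i)
  })
}

#' Random synthetic signature matrix
#'
#' Generates S probability profiles over the 96 contexts with sparse,
#' peaky mass (Gamma(0.15) weights, normalized), which makes signatures
#' mutually distinguishable the way real mutational signatures are. Used
#' as the default signature set for simulation and as a stand-in fixture
#' where curated signature catalogs are unavailable.
#'
#' @param n_signatures number of signatures.
#' @param seed RNG seed.
#' @param ids signature IDs (default S1..Sn).
#' @return a \code{signature_matrix}.
#' @export
synthetic_signature_matrix <- function(n_signatures = 12, seed = 1,
                                       ids = paste0("S", seq_len(n_signatures))) {
  set.seed(seed)
  W <- matrix(stats::rgamma(96 * n_signatures, shape = 0.15), nrow = 96)
  W <- sweep(W, 2, colSums(W), "/")
  rownames(W) <- context_labels_96()
  colnames(W) <- ids
  as_signature_matrix(W)
}

#' Draw a 96-context catalog from signature exposures
#'
#' Multinomial draw of n mutation contexts from the mixture distribution
#' W e, the generative inverse of the NNLS decomposition.
#'
#' @param W a \code{signature_matrix}.
#' @param e_norm non-negative exposure fractions over W's signatures,
#'   summing to 1.
#' @param n number of mutations.
#' @param seed RNG seed (NULL = use current RNG state).
#' @return a \code{catalog96} (named counts over the 96 contexts).
#' @export
generate_catalog_from_exposures <- function(W, e_norm, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(W, "signature_matrix"), n >= 0)
  if (any(e_norm < 0)) stop("negative exposure")
  if (abs(sum(e_norm) - 1) > 1e-9) stop("exposures must sum to 1")
  p <- as.vector(W$W %*% e_norm)
  counts <- if (n == 0) integer(96) else
    as.vector(stats::rmultinom(1, n, p))
  as_catalog96(stats::setNames(counts, W$contexts))
}

#' Simulate sequencing read counts at a variant site
#'
#' Depth is Poisson(mean_coverage) truncated at >= 1; the alternate-allele
#' count is Binomial(depth, true_vaf).
#'
#' @param true_vaf true variant allele fraction(s) in [0, 1]; recycled.
#' @param mean_coverage mean depth.
#' @param n number of sites (default length of true_vaf).
#' @param seed RNG seed (NULL = current state).
#' @return data.frame with columns \code{depth} and \code{alt_count}.
#' @export
simulate_read_counts <- function(true_vaf, mean_coverage, n = length(true_vaf),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(true_vaf >= 0 & true_vaf <= 1), mean_coverage > 0)
  true_vaf <- rep_len(true_vaf, n)
  depth <- stats::rpois(n, mean_coverage)
  depth[depth < 1] <- 1L
  alt <- stats::rbinom(n, depth, true_vaf)
  data.frame(depth = depth, alt_count = alt)
}

#' Expected clonal variant allele fraction
#'
#' For a single-copy clonal variant in a sample of given purity and local
#' total copy number: purity * mult / (purity * cn + 2 * (1 - purity)).
#' For a pure diploid sample (purity 1, cn 2, mult 1) this is exactly 0.5.
#'
#' @param purity tumor cell content in (0, 1].
#' @param cn local total copy number in tumor cells.
#' @param mult variant multiplicity (copies carrying the variant).
#' @return expected VAF.
#' @export
expected_vaf <- function(purity, cn, mult = 1) {
  stopifnot(all(purity > 0), all(purity <= 1), all(cn > 0), all(mult > 0))
  purity * mult / (purity * cn + 2 * (1 - purity))
}

draw_positions <- function(n, genome) {
  out <- data.frame(chrom = character(), pos = numeric(),
                    stringsAsFactors = FALSE)
  need <- n
  while (need > 0) {
    m <- need + 10L
    ci <- sample.int(nrow(genome), m, replace = TRUE, prob = genome$length)
    pos <- floor(stats::runif(m, 1, genome$length[ci] + 1))
    out <- rbind(out, data.frame(chrom = genome$chrom[ci], pos = pos,
                                 stringsAsFactors = FALSE))
    out <- out[!duplicated(paste(out$chrom, out$pos)), , drop = FALSE]
    need <- n - nrow(out)
  }
  rownames(out) <- NULL
  out[seq_len(n), , drop = FALSE]
}

draw_stratum_variants <- function(n, e_norm, W) {
  sig_ids <- W$signature_ids
  if (is.null(e_norm)) {
    e_norm <- stats::setNames(numeric(length(sig_ids)), sig_ids)
    active <- sample(sig_ids, min(3, length(sig_ids)))
    w <- stats::rgamma(length(active), 1)
    e_norm[active] <- w / sum(w)
  }
  e_norm <- e_norm[sig_ids]
  sig <- sample(sig_ids, n, replace = TRUE, prob = e_norm)
  ctx_label <- vapply(sig, function(s) {
    sample(W$contexts, 1, prob = W$W[, s])
  }, character(1))
  parts <- parse_context_label(ctx_label)
  data.frame(signature_id = sig, ref = parts$ref, alt = parts$alt,
             context = parts$context, stringsAsFactors = FALSE)
}

#' Generate one synthetic trio with truth labels
#'
#' Produces aligned normal/tumor/metastasis read counts for a configurable
#' number of somatic SNVs partitioned into truncal, tumor-private and
#' metastasis-private strata, plus germline heterozygous positions.
#' Truncal variants are present in both tumor and metastasis at the
#' expected clonal VAF of each sample; private variants in one sample
#' only. A configurable fraction of truncal variants is contaminated:
#' their reads leak into the matched normal (normal VAF uniform in
#' (0.01, 0.15)) and the upstream caller consequently labels them germline
#' (caller-somatic FALSE) — the miscalls tumor-in-normal rescue must
#' recover. The upstream caller is emulated as requiring >= 2 alternate
#' reads in a sample to call a variant there.
#'
#' @param config a \code{trio_config}.
#' @param W a \code{signature_matrix} whose IDs cover the config exposures.
#' @param seed RNG seed (default \code{config$seed}).
#' @return a \code{trio_simulation}: list with \code{trio} (a
#'   \code{trio_dataset}) and \code{truth} (per-variant stratum,
#'   generating signature, contamination flag, kataegis locus id).
#' @export
generate_trio <- function(config, W, seed = config$seed) {
  stopifnot(inherits(config, "trio_config"), inherits(W, "signature_matrix"))
  set.seed(seed)
  n_strat <- as.vector(stats::rmultinom(1, config$n_snvs, config$fractions))
  names(n_strat) <- names(config$fractions)

  loc <- draw_positions(sum(n_strat) + config$n_germline, config$genome)
  som_loc <- loc[seq_len(sum(n_strat)), , drop = FALSE]
  germ_loc <- loc[-seq_len(sum(n_strat)), , drop = FALSE]

  stratum <- rep(names(n_strat), n_strat)
  pieces <- lapply(names(n_strat), function(s) {
    draw_stratum_variants(n_strat[[s]], config$exposures[[s]], W)
  })
  alle <- do.call(rbind, pieces)

  vaf_t <- expected_vaf(config$purity_tumor, config$ploidy_tumor)
  vaf_m <- expected_vaf(config$purity_met, config$ploidy_met)
  in_tumor <- stratum != "met_private"
  in_met <- stratum != "tumor_private"

  n_som <- sum(n_strat)
  contaminated <- rep(FALSE, n_som)
  idx_truncal <- which(stratum == "truncal")
  n_cont <- floor(config$contamination_fraction * length(idx_truncal))
  if (n_cont > 0)
    contaminated[sample(idx_truncal, n_cont)] <- TRUE

  tum <- simulate_read_counts(ifelse(in_tumor, vaf_t, 0),
                              config$mean_coverage, n_som)
  met <- simulate_read_counts(ifelse(in_met, vaf_m, 0),
                              config$mean_coverage, n_som)
  normal_vaf <- ifelse(contaminated, stats::runif(n_som, 0.01, 0.15), 0)
  nor <- simulate_read_counts(normal_vaf, config$mean_coverage, n_som)

  tumor_somatic <- in_tumor & tum$alt_count >= 2 & !contaminated
  met_somatic <- in_met & met$alt_count >= 2 & !contaminated

  som <- data.frame(
    chrom = som_loc$chrom, pos = som_loc$pos, ref = alle$ref,
    alt = alle$alt, context = alle$context,
    normal_ref = nor$depth - nor$alt_count, normal_alt = nor$alt_count,
    tumor_ref = tum$depth - tum$alt_count, tumor_alt = tum$alt_count,
    met_ref = met$depth - met$alt_count, met_alt = met$alt_count,
    tumor_somatic = tumor_somatic, met_somatic = met_somatic,
    germline = contaminated, stringsAsFactors = FALSE)

  germ <- NULL
  common_positions <- character()
  if (config$n_germline > 0) {
    ng <- config$n_germline
    bases <- c("A", "C", "G", "T")
    gref <- sample(bases, ng, replace = TRUE)
    galt <- vapply(gref, function(b) sample(setdiff(bases, b), 1),
                   character(1))
    gn <- simulate_read_counts(rep(0.5, ng), config$mean_coverage, ng)
    gt <- simulate_read_counts(rep(0.5, ng), config$mean_coverage, ng)
    gm <- simulate_read_counts(rep(0.5, ng), config$mean_coverage, ng)
    germ <- data.frame(
      chrom = germ_loc$chrom, pos = germ_loc$pos, ref = gref, alt = galt,
      context = NA_character_,
      normal_ref = gn$depth - gn$alt_count, normal_alt = gn$alt_count,
      tumor_ref = gt$depth - gt$alt_count, tumor_alt = gt$alt_count,
      met_ref = gm$depth - gm$alt_count, met_alt = gm$alt_count,
      tumor_somatic = FALSE, met_somatic = FALSE, germline = TRUE,
      stringsAsFactors = FALSE)
    is_common <- stats::runif(ng) < config$common_fraction
    common_positions <- paste0(germ$chrom[is_common], ":",
                               germ$pos[is_common])
  }

  calls <- rbind(som, germ)
  rownames(calls) <- NULL

  trio <- structure(list(
    patient_id = config$patient_id, calls = calls,
    purity_tumor = config$purity_tumor, purity_met = config$purity_met,
    ploidy_tumor = config$ploidy_tumor, ploidy_met = config$ploidy_met,
    mean_coverage = config$mean_coverage,
    common_positions = common_positions), class = "trio_dataset")

  truth <- data.frame(
    chrom = som$chrom, pos = som$pos, ref = som$ref, alt = som$alt,
    stratum = stratum, signature_id = alle$signature_id,
    contaminated = contaminated, kataegis_locus = NA_character_,
    stringsAsFactors = FALSE)

  structure(list(trio = trio, truth = truth, config = config),
            class = "trio_simulation")
}

#' Inject kataegis clusters into a simulated trio
#'
#' Adds \code{n_loci} clusters of \code{cluster_size} truncal SNVs whose
#' positions span at most \code{span} bp, recording the locus ID in the
#' truth table.
#'
#' @param sim a \code{trio_simulation}.
#' @param n_loci number of clusters to add.
#' @param cluster_size mutations per cluster (>= 2).
#' @param span maximum span in bp (>= cluster_size - 1 so that
#'   cluster_size distinct positions fit).
#' @param seed RNG seed.
#' @return the modified \code{trio_simulation}.
#' @export
inject_kataegis <- function(sim, n_loci, cluster_size = 6, span = 5000,
                            seed = 1) {
  stopifnot(inherits(sim, "trio_simulation"), cluster_size >= 2)
  if (span < cluster_size - 1)
    stop("span too small for ", cluster_size, " distinct positions")
  if (n_loci == 0) return(sim)
  set.seed(seed)
  config <- sim$config
  genome <- config$genome
  W_labels <- context_labels_96()
  vaf_t <- expected_vaf(config$purity_tumor, config$ploidy_tumor)
  vaf_m <- expected_vaf(config$purity_met, config$ploidy_met)
  for (l in seq_len(n_loci)) {
    ci <- sample.int(nrow(genome), 1, prob = genome$length)
    start <- floor(stats::runif(1, 1, genome$length[ci] - span))
    offs <- sort(sample(0:span, cluster_size))
    offs <- offs - offs[1]                 # anchor first member at start
    pos <- start + offs
    label <- sample(W_labels, cluster_size, replace = TRUE)
    parts <- parse_context_label(label)
    tum <- simulate_read_counts(rep(vaf_t, cluster_size),
                                config$mean_coverage, cluster_size)
    met <- simulate_read_counts(rep(vaf_m, cluster_size),
                                config$mean_coverage, cluster_size)
    nor <- simulate_read_counts(rep(0, cluster_size),
                                config$mean_coverage, cluster_size)
    add <- data.frame(
      chrom = genome$chrom[ci], pos = pos, ref = parts$ref,
      alt = parts$alt, context = parts$context,
      normal_ref = nor$depth, normal_alt = 0L,
      tumor_ref = tum$depth - tum$alt_count, tumor_alt = tum$alt_count,
      met_ref = met$depth - met$alt_count, met_alt = met$alt_count,
      tumor_somatic = tum$alt_count >= 2, met_somatic = met$alt_count >= 2,
      germline = FALSE, stringsAsFactors = FALSE)
    sim$trio$calls <- rbind(sim$trio$calls, add)
    sim$truth <- rbind(sim$truth, data.frame(
      chrom = add$chrom, pos = add$pos, ref = add$ref, alt = add$alt,
      stratum = "truncal", signature_id = NA_character_,
      contaminated = FALSE, kataegis_locus = sprintf("k%d", l),
      stringsAsFactors = FALSE))
  }
  sim
}

#' Synthetic allele-specific copy-number segments for one sample
#'
#' Tiles each chromosome of the genome model with 2-4 segments whose total
#' copy number is the sample base ploidy plus an occasional integer gain or
#' loss (with mild jitter), and assigns minor-allele copy numbers with
#' occasional LOH.
#'
#' @param sample_id sample label.
#' @param ploidy sample base ploidy.
#' @param genome genome model data.frame.
#' @param seed RNG seed.
#' @return a \code{cn_segments} table.
#' @export
synthetic_segments <- function(sample_id, ploidy,
                               genome = default_genome_model(), seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(genome))) {
    n_seg <- sample(2:4, 1)
    cuts <- sort(sample.int(genome$length[i] - 1, n_seg - 1))
    bounds <- c(1, cuts + 1)
    ends <- c(cuts, genome$length[i])
    for (j in seq_len(n_seg)) {
      delta <- sample(c(-1, 0, 0, 0, 1), 1)
      tcn <- max(0, ploidy + delta + stats::rnorm(1, 0, 0.05))
      minor <- max(0, min(floor(tcn / 2),
                          sample(0:1, 1, prob = c(0.2, 0.8))))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, chrom = genome$chrom[i],
        start = bounds[j], end = ends[j], tcn = tcn, minor_cn = minor,
        stringsAsFactors = FALSE)
    }
  }
  as_cn_segments(do.call(rbind, rows))
}

#' Simulate a whole synthetic cohort
#'
#' Convenience wrapper: draws per-patient configurations with
#' \code{\link{crc_cohort_configs}} and generates each trio.
#'
#' @param n_patients number of trios.
#' @param W signature matrix (default: synthetic 12-signature matrix).
#' @param seed master seed.
#' @param ... passed to \code{\link{crc_cohort_configs}}.
#' @return list with \code{sims} (list of \code{trio_simulation}) and
#'   \code{W}.
#' @export
simulate_cohort <- function(n_patients = 12, W = NULL, seed = 1, ...) {
  if (is.null(W)) W <- synthetic_signature_matrix(12, seed = seed)
  configs <- crc_cohort_configs(n_patients = n_patients,
                                  signature_ids = W$signature_ids,
                                  seed = seed, ...)
  sims <- lapply(configs, generate_trio, W = W)
  list(sims = sims, W = W)
}
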