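RESULT_SECTIONS <- c("tinda", "stratification", "signatures", "kataegis",
                     "copy_number", "recurrence", "mutual_exclusivity",
                     "strata_comparison")

DEFAULT_PARAMS <- list(
  maf_threshold = 0.05, alt_floor = 2, germline_ratio = 2,
  tinda_k = 9, tinda_above_frac = 0.75, tinda_maf_min = 0.01,
  tinda_control_max = 0.45, kataegis_k = 5, kataegis_window = 10000,
  cna_threshold = 0.7, signature_cutoff = 0.06, recurrence_min_samples = 4,
  seed = 1)

#' Parse a flat key = value run configuration file
#'
#' Lines of the form \code{key = value}; blank lines and lines starting
#' with \code{#} are ignored. Values that parse as numbers become
#' numeric.
#'
#' @param path config file.
#' @return named list.
#' @export
parse_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (l in lines) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", l)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Write a synthetic cohort to disk
#'
#' Generates a preset (colorectal trio cohort) synthetic dataset and writes one
#' directory per patient (trio calls, truth labels, metadata,
#' tumor/metastasis copy-number segments, common-variant positions) plus
#' cohort-level files: the signature matrix, gene models and arm
#' definitions.
#'
#' @param out_dir output directory (created).
#' @param n_patients number of trios (default 12).
#' @param n_snvs fixed per-patient SNV count or NULL for the preset draw.
#' @param seed master seed.
#' @return out_dir, invisibly.
#' @export
simulate_command <- function(out_dir, n_patients = 12, n_snvs = NULL,
                             seed = 1) {
  cohort <- simulate_cohort(n_patients = n_patients, n_snvs = n_snvs,
                            seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_signature_matrix(cohort$W, file.path(out_dir, "signatures.tsv"))
  genome <- default_genome_model()
  models <- synthetic_gene_models(seed = seed)
  write_gene_models(models, file.path(out_dir, "gene_models.bed"))
  arms <- default_arm_map(genome)
  write.table(as.data.frame(arms), file.path(out_dir, "arms.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (i in seq_along(cohort$sims)) {
    sim <- cohort$sims[[i]]
    pd <- file.path(out_dir, sim$trio$patient_id)
    dir.create(pd, showWarnings = FALSE)
    write.table(sim$trio$calls, file.path(pd, "calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(sim$truth, file.path(pd, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(sim$trio$common_positions,
               file.path(pd, "common_variants.txt"))
    meta <- data.frame(
      patient_id = sim$trio$patient_id,
      purity_tumor = sim$trio$purity_tumor,
      purity_met = sim$trio$purity_met,
      ploidy_tumor = sim$trio$ploidy_tumor,
      ploidy_met = sim$trio$ploidy_met,
      mean_coverage = sim$trio$mean_coverage)
    write.table(meta, file.path(pd, "meta.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_segments(
      synthetic_segments(paste0(sim$trio$patient_id, "_T"),
                         sim$trio$ploidy_tumor, genome, seed = seed + 100 + i),
      file.path(pd, "segments_tumor.tsv"))
    write_segments(
      synthetic_segments(paste0(sim$trio$patient_id, "_M"),
                         sim$trio$ploidy_met, genome, seed = seed + 200 + i),
      file.path(pd, "segments_met.tsv"))
  }
  invisible(out_dir)
}

#' Synthetic gene models
#'
#' Random single-exon gene structures (CDS + 3'-UTR + flanking intron for
#' coding genes, ncRNA_exon for non-coding ones) scattered over the
#' genome model; a stand-in for real transcript annotation in synthetic
#' runs.
#'
#' @param n_genes number of genes.
#' @param genome genome model.
#' @param seed RNG seed.
#' @return a \code{gene_model_set}.
#' @export
synthetic_gene_models <- function(n_genes = 300,
                                  genome = default_genome_model(),
                                  seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_genes)) {
    ci <- sample.int(nrow(genome), 1, prob = genome$length)
    start <- floor(stats::runif(1, 1, genome$length[ci] - 2e5))
    gid <- sprintf("G%04d", i)
    if (stats::runif(1) < 0.75) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = genome$chrom[ci],
        start = c(start, start + 3000, start + 10000),
        end = c(start + 2000, start + 9999, start + 12000),
        gene_id = gid, strand = "+",
        region_class = c("CDS", "intron", "UTR3"),
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = genome$chrom[ci], start = start, end = start + 3000,
        gene_id = gid, strand = "+", region_class = "ncRNA_exon",
        stringsAsFactors = FALSE)
    }
  }
  as_gene_model_set(do.call(rbind, rows))
}

#' Read one patient directory written by simulate_command
#'
#' @param path patient directory.
#' @return a \code{trio_dataset} (with truth attached as attribute
#'   \code{"truth"} when present).
#' @export
read_trio_dir <- function(path) {
  meta <- read.table(file.path(path, "meta.tsv"), header = TRUE,
                     stringsAsFactors = FALSE)
  calls <- read.table(file.path(path, "calls.tsv"), header = TRUE,
                      stringsAsFactors = FALSE,
                      colClasses = c(chrom = "character"))
  common <- character()
  cf <- file.path(path, "common_variants.txt")
  if (file.exists(cf)) common <- readLines(cf)
  trio <- structure(list(
    patient_id = meta$patient_id, calls = calls,
    purity_tumor = meta$purity_tumor, purity_met = meta$purity_met,
    ploidy_tumor = meta$ploidy_tumor, ploidy_met = meta$ploidy_met,
    mean_coverage = meta$mean_coverage, common_positions = common),
    class = "trio_dataset")
  tf <- file.path(path, "truth.tsv")
  if (file.exists(tf))
    attr(trio, "truth") <- read.table(tf, header = TRUE,
                                      stringsAsFactors = FALSE,
                                      colClasses = c(chrom = "character"))
  trio
}

.stratum_catalogs <- function(strat) {
  snv <- strat$calls[strat$calls$is_snv, , drop = FALSE]
  lapply(stats::setNames(nm = c("shared", "tumor_private", "met_private")),
         function(s) build_catalog(snv[snv$stratum == s, , drop = FALSE]))
}

#' Run the full trio analysis pipeline
#'
#' Orchestrates, per patient: tumor-in-normal rescue, stratification,
#' per-stratum catalog construction; and at cohort level: signature
#' detection and per-stratum exposure fits, strata comparison statistics,
#' kataegis detection, copy-number state and arm recurrence, mutation
#' matrices with recurrence and mutual-exclusivity tests. Writes a
#' machine-readable JSON summary, TSV tables and a run log to the output
#' directory; stages whose inputs are absent are marked "skipped".
#'
#' @param data_dir cohort directory as written by
#'   \code{\link{simulate_command}} (or assembled in the same layout).
#' @param out_dir output directory.
#' @param params named list overriding entries of the documented
#'   parameter defaults (MAF threshold 0.05, 2-read floor, germline ratio
#'   2, 9 TiNDA clusters with 0.75/0.01/0.45 rules, kataegis 5/10 kb, CNA
#'   threshold 0.7, signature cutoff 0.06, recurrence cutoff 4, seed 1).
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(data_dir, out_dir, params = list()) {
  p <- utils::modifyList(DEFAULT_PARAMS, params)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log <- function(...) cat(..., "\n", sep = "", file = log_path,
                           append = TRUE)
  cat("", file = log_path)
  log("metatrio run; parameters:")
  for (k in names(p)) log("  ", k, " = ", format(p[[k]]))

  W <- read_signature_matrix(file.path(data_dir, "signatures.tsv"))
  models_path <- file.path(data_dir, "gene_models.bed")
  models <- if (file.exists(models_path)) read_gene_models(models_path)
    else NULL
  arms_path <- file.path(data_dir, "arms.tsv")
  arms <- if (file.exists(arms_path)) read_arms(arms_path) else NULL

  patient_dirs <- list.dirs(data_dir, recursive = FALSE)
  patient_dirs <- patient_dirs[file.exists(file.path(patient_dirs,
                                                     "calls.tsv"))]
  if (length(patient_dirs) == 0) stop("stage input: no patient directories in ",
                                      data_dir)

  tinda_section <- list()
  strat_section <- list()
  kataegis_section <- list()
  catalogs <- list()
  strats <- list()
  trios <- list()
  all_segments <- NULL
  ploidies <- c()

  for (pd in patient_dirs) {
    trio <- read_trio_dir(pd)
    id <- trio$patient_id
    tin <- apply_tinda(trio, k = p$tinda_k, seed = p$seed,
                       above_frac = p$tinda_above_frac,
                       maf_min = p$tinda_maf_min,
                       control_max = p$tinda_control_max)
    trios[[id]] <- tin$trio
    tinda_section[[id]] <- list(n_rescued = nrow(tin$audit))
    strat <- stratify_trio(tin$trio, maf_threshold = p$maf_threshold,
                           alt_floor = p$alt_floor,
                           germline_ratio = p$germline_ratio)
    strats[[id]] <- strat
    strat_section[[id]] <- as.list(strat$fractions)
    catalogs[[id]] <- .stratum_catalogs(strat)

    snv <- strat$calls[strat$calls$is_snv, ]
    kat_t <- detect_kataegis(snv[snv$present_tumor, c("chrom", "pos")],
                             k = p$kataegis_k, window = p$kataegis_window)
    kat_m <- detect_kataegis(snv[snv$present_met, c("chrom", "pos")],
                             k = p$kataegis_k, window = p$kataegis_window)
    if (!is.null(models)) {
      kat_t <- annotate_locus_proximity(kat_t, models)
      kat_m <- annotate_locus_proximity(kat_m, models)
    }
    kataegis_section[[id]] <- list(tumor_loci = nrow(kat_t),
                                   met_loci = nrow(kat_m))

    for (role in c("tumor", "met")) {
      sf <- file.path(pd, paste0("segments_", role, ".tsv"))
      if (file.exists(sf)) {
        seg <- read_segments(sf)
        all_segments <- rbind(all_segments, as.data.frame(seg))
        ploidies[unique(seg$sample_id)] <-
          if (role == "tumor") trio$ploidy_tumor else trio$ploidy_met
      }
    }
    log("patient ", id, ": ", nrow(tin$audit), " rescued, ",
        strat$n_snvs, " SNVs stratified")
  }

  # cohort-level signature detection on pooled catalogs, then restricted
  # per-stratum fits
  flat <- unlist(catalogs, recursive = FALSE)
  nonzero <- flat[vapply(flat, catalog_total, numeric(1)) > 0]
  active <- cohort_signature_detection(nonzero, W, p$signature_cutoff)
  Wr <- restrict_signatures(W, active)
  exposures <- list()
  for (id in names(catalogs)) {
    exposures[[id]] <- lapply(catalogs[[id]], function(cat) {
      if (catalog_total(cat) == 0) return(NULL)
      suppressWarnings(apply_signature_cutoffs(cat, Wr, p$signature_cutoff))
    })
  }
  signatures_section <- list(
    active = active,
    normalized = lapply(exposures, function(e)
      lapply(e[!vapply(e, is.null, logical(1))],
             function(x) as.list(round(x$normalized, 4)))))

  complete <- names(exposures)[vapply(exposures, function(e)
    !any(vapply(e, is.null, logical(1))), logical(1))]
  strata_comparison <- "skipped"
  if (length(complete) >= 3) {
    mats <- lapply(stats::setNames(nm = c("shared", "tumor_private",
                                          "met_private")), function(s) {
      do.call(rbind, lapply(complete, function(id)
        exposures[[id]][[s]]$normalized))
    })
    strata_comparison <- compare_strata_exposures(mats)
    write.table(strata_comparison,
                file.path(out_dir, "strata_comparison.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    strata_comparison <- split(strata_comparison, seq_len(nrow(strata_comparison)))
    strata_comparison <- lapply(strata_comparison, as.list)
  }

  recurrence <- "skipped"
  mutex <- "skipped"
  if (!is.null(models)) {
    ann_list <- lapply(names(strats), function(id) {
      snv <- strats[[id]]$calls
      ann <- annotate_variants(snv, models)
      rbind(
        cbind(ann[ann$present_tumor, ], sample_id = paste0(id, "_T")),
        cbind(ann[ann$present_met, ], sample_id = paste0(id, "_M")))
    })
    ann_all <- do.call(rbind, ann_list)
    mat <- build_mutation_matrix(ann_all, "coding_nonsilent")
    rec <- recurrent_genes(mat, min_samples = p$recurrence_min_samples)
    write.table(rec, file.path(out_dir, "recurrent_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    recurrence <- list(channel = "coding_nonsilent",
                       n_genes = nrow(rec),
                       genes = rec$gene)
    top <- utils::head(rec$gene, 10)
    mutex <- list()
    if (length(top) >= 2) {
      prs <- utils::combn(top, 2, simplify = FALSE)
      for (pr in prs) {
        me <- mutual_exclusivity(mat, pr[1], pr[2])
        mutex[[paste(pr, collapse = "|")]] <-
          list(overlap = me$overlap, exclusive = me$exclusive,
               fisher_p = me$fisher_p)
      }
    }
  }

  copy_number <- "skipped"
  if (!is.null(all_segments) && !is.null(arms)) {
    seg_states <- annotate_cna_states(as_cn_segments(all_segments),
                                      ploidies,
                                      threshold = p$cna_threshold)
    arm_rec <- arm_recurrence(seg_states, arms)
    write.table(arm_rec, file.path(out_dir, "arm_recurrence.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    copy_number <- lapply(split(arm_rec, seq_len(nrow(arm_rec))), as.list)
  }

  summary <- list(
    schema_version = "1.0",
    parameters = p,
    tinda = tinda_section,
    stratification = strat_section,
    signatures = signatures_section,
    kataegis = kataegis_section,
    copy_number = copy_number,
    recurrence = recurrence,
    mutual_exclusivity = mutex,
    strata_comparison = strata_comparison)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log("done; summary written")
  invisible(summary)
}

#' Validate an input file
#'
#' Dispatch on the file name: variant tables, gene models, signature
#' matrices, segments and arm maps are read with their strict readers;
#' success means the file is valid.
#'
#' @param path file to validate.
#' @return TRUE invisibly on success; errors describe the problem.
#' @export
validate_input <- function(path) {
  base <- basename(path)
  if (grepl("\\.bed$", base)) read_gene_models(path)
  else if (grepl("signature", base)) read_signature_matrix(path)
  else if (grepl("segment", base)) read_segments(path)
  else if (grepl("arm", base)) read_arms(path)
  else if (grepl("\\.vcf$", base)) read_variant_table(path, "vcf_subset")
  else read_variant_table(path, "tsv")
  invisible(TRUE)
}
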