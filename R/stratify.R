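#' Expected read support for a single-copy clonal variant
#'
#' purity x coverage / ploidy: at the cohort medians (purity 0.475,
#' coverage 36, ploidy 3) a single-copy clonal variant is expected to be
#' covered by 5.7 mutant reads, which motivates the fixed 2-read rescue
#' floor.
#'
#' @param purity tumor cell content (> 0).
#' @param coverage mean sequencing depth (> 0).
#' @param ploidy sample base ploidy (> 0).
#' @return expected mutant read count.
#' @export
expected_read_support <- function(purity, coverage, ploidy) {
  if (any(purity <= 0) || any(coverage <= 0) || any(ploidy <= 0))
    stop("purity, coverage and ploidy must all be positive")
  purity * coverage / ploidy
}

#' Poisson probability of observing exactly k supporting reads
#'
#' The Poisson point mass e^(-mu) mu^k / k!, used to reason about how
#' likely a given read support is under an expected support mu.
#'
#' @param k observed read count (non-negative integer).
#' @param mu expected read support (> 0).
#' @return P(X = k) under Poisson(mu).
#' @export
poisson_support_probability <- function(k, mu) {
  if (any(k < 0)) stop("k must be non-negative")
  if (any(mu <= 0)) stop("mu must be positive")
  stats::dpois(k, mu)
}

#' Minimum alternate reads exceeding a MAF threshold
#'
#' Smallest integer r with r / coverage strictly greater than the MAF
#' threshold; at 36x and a 5% threshold this is 2 reads. Diagnostic
#' companion to the fixed 2-read rescue floor.
#'
#' @param coverage read depth (>= 1).
#' @param maf_threshold threshold in (0, 1).
#' @return integer read count.
#' @export
min_alt_reads_for_maf <- function(coverage, maf_threshold) {
  stopifnot(coverage >= 1, maf_threshold > 0, maf_threshold < 1)
  as.integer(floor(coverage * maf_threshold) + 1)
}

.sample_maf <- function(calls, sample) {
  alt <- calls[[paste0(sample, "_alt")]]
  depth <- alt + calls[[paste0(sample, "_ref")]]
  ifelse(depth > 0, alt / depth, 0)
}

# vectorized cross-rescue presence over rows of a trio's calls
.presence <- function(calls, maf_threshold, alt_floor, germline_ratio) {
  maf_t <- .sample_maf(calls, "tumor")
  maf_m <- .sample_maf(calls, "met")
  maf_n <- .sample_maf(calls, "normal")
  rescue_t <- maf_t > maf_threshold & calls$tumor_alt >= alt_floor &
    maf_t >= germline_ratio * maf_n
  rescue_m <- maf_m > maf_threshold & calls$met_alt >= alt_floor &
    maf_m >= germline_ratio * maf_n
  list(
    tumor = calls$tumor_somatic | (calls$met_somatic & rescue_t),
    met = calls$met_somatic | (calls$tumor_somatic & rescue_m)
  )
}

#' Cross-rescue presence of one variant in the tumor/metastasis pair
#'
#' A variant called somatic in one sample of the pair is granted presence
#' in the other sample when, there, its MAF exceeds the threshold
#' (strictly), it is supported by at least \code{alt_floor} reads, and its
#' MAF is at least \code{germline_ratio} times the matched control MAF
#' (a control MAF of 0 satisfies the ratio). Presence by direct somatic
#' call is always retained.
#'
#' @param variant_key string "chrom:pos:ref:alt".
#' @param trio a \code{trio_dataset}.
#' @param maf_threshold MAF threshold (default 0.05, strict).
#' @param alt_floor fixed minimum alternate reads (default 2).
#' @param germline_ratio minimum sample/control MAF ratio (default 2,
#'   non-strict).
#' @return named logical vector (present_tumor, present_met).
#' @export
rescue_in_pair <- function(variant_key, trio, maf_threshold = 0.05,
                           alt_floor = 2, germline_ratio = 2) {
  parts <- strsplit(variant_key, ":", fixed = TRUE)[[1]]
  calls <- trio$calls
  row <- calls[calls$chrom == parts[1] & calls$pos == as.numeric(parts[2]) &
                 calls$ref == parts[3] & calls$alt == parts[4], ,
               drop = FALSE]
  if (nrow(row) == 0) stop("variant not found in trio: ", variant_key)
  if (!row$tumor_somatic && !row$met_somatic)
    stop("variant not called somatic in either sample: ", variant_key)
  p <- .presence(row, maf_threshold, alt_floor, germline_ratio)
  c(present_tumor = p$tumor, present_met = p$met)
}

#' Assign the stratum implied by pairwise presence
#'
#' @param present_tumor,present_met logical presence flags; at least one
#'   must be TRUE.
#' @return \code{"shared"}, \code{"tumor_private"} or \code{"met_private"}.
#' @export
assign_stratum <- function(present_tumor, present_met) {
  if (any(!present_tumor & !present_met))
    stop("variant present in neither sample has no stratum")
  ifelse(present_tumor & present_met, "shared",
         ifelse(present_tumor, "tumor_private", "met_private"))
}

#' Stratify a trio's somatic variants
#'
#' Applies the MAF cross-rescue rule to every somatic variant of the trio
#' and partitions the union of somatic calls into shared (truncal),
#' tumor-private and metastasis-private strata. Fractions are reported
#' over the union of somatic SNVs; indels (if present) receive strata
#' under the same rules but are flagged as an extension and excluded from
#' the fractions.
#'
#' @param trio a \code{trio_dataset}.
#' @param maf_threshold,alt_floor,germline_ratio rescue parameters; see
#'   \code{\link{rescue_in_pair}}.
#' @return a \code{stratified_catalog}: list with \code{calls} (somatic
#'   union with stratum and presence flags) and \code{fractions} (named,
#'   summing to 1 over SNVs).
#' @export
stratify_trio <- function(trio, maf_threshold = 0.05, alt_floor = 2,
                          germline_ratio = 2) {
  calls <- trio$calls
  som <- calls[calls$tumor_somatic | calls$met_somatic, , drop = FALSE]
  if (nrow(som) == 0) stop("trio has no somatic calls to stratify")
  p <- .presence(som, maf_threshold, alt_floor, germline_ratio)
  som$present_tumor <- p$tumor
  som$present_met <- p$met
  som$stratum <- assign_stratum(p$tumor, p$met)
  som$is_snv <- nchar(som$ref) == 1L & nchar(som$alt) == 1L
  snv <- som[som$is_snv, , drop = FALSE]
  fractions <- c(shared = mean(snv$stratum == "shared"),
                 tumor_private = mean(snv$stratum == "tumor_private"),
                 met_private = mean(snv$stratum == "met_private"))
  structure(list(patient_id = trio$patient_id, calls = som,
                 fractions = fractions, n_snvs = nrow(snv)),
            class = "stratified_catalog")
}

#' @export
print.stratified_catalog <- function(x, ...) {
  cat("Stratified somatic catalog:", x$patient_id, "\n")
  cat(sprintf("  %d somatic SNVs: %.1f%% shared, %.1f%% tumor-private, %.1f%% metastasis-private\n",
              x$n_snvs, 100 * x$fractions["shared"],
              100 * x$fractions["tumor_private"],
              100 * x$fractions["met_private"]))
  invisible(x)
}

#' Somatic mutation rate per megabase
#'
#' n_snvs / (mappable_bases / 1e6), reported to one decimal: 17,189 SNVs
#' over a 2.8 Gb mappable genome is 6.1 mutations per Mb.
#'
#' @param n_snvs somatic SNV count.
#' @param mappable_bases mappable genome size in bp (> 0).
#' @return mutations per Mb, rounded to 1 decimal.
#' @export
mutation_rate_per_mb <- function(n_snvs, mappable_bases) {
  stopifnot(mappable_bases > 0, n_snvs >= 0)
  round(n_snvs / (mappable_bases / 1e6), 1)
}

MMR_GENES <- c("MLH1", "MLH3", "MSH2", "MSH3", "MSH6", "PMS2")

#' Microsatellite-stability gene check
#'
#' Flags whether a sample carries non-silent mutations of interest in the
#' DNA mismatch-repair genes (MLH1, MLH3, MSH2, MSH3, MSH6, PMS2 —
#' suggesting hypermutator status) or in POLE (suggesting ultra-mutator
#' status).
#'
#' @param annotated annotated mutations of one sample (needs gene_ids and
#'   mutation_of_interest columns).
#' @param mmr_genes mismatch-repair gene list.
#' @param pole_gene polymerase-epsilon gene name.
#' @return named logical vector (mmr_hit, pole_hit).
#' @export
classify_sample_msi_pole <- function(annotated, mmr_genes = MMR_GENES,
                                     pole_gene = "POLE") {
  moi <- annotated[annotated$mutation_of_interest %in% TRUE, , drop = FALSE]
  genes <- unlist(strsplit(moi$gene_ids, ",", fixed = TRUE))
  c(mmr_hit = any(genes %in% mmr_genes),
    pole_hit = any(genes %in% pole_gene))
}
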