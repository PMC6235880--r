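#' Call the copy-number state of segments relative to base ploidy
#'
#' Gain when tcn - base_ploidy > threshold, loss when base_ploidy - tcn >
#' threshold (both strict, default 0.7), otherwise neutral. A deviation of
#' exactly the threshold is neutral.
#'
#' @param tcn total copy number (vector).
#' @param base_ploidy sample base ploidy (> 0).
#' @param threshold deviation threshold (default 0.7).
#' @return character vector: "gain", "loss" or "neutral".
#' @export
call_cna_state <- function(tcn, base_ploidy, threshold = 0.7) {
  stopifnot(base_ploidy > 0)
  # strict inequality with a guard against floating-point representation
  # error, so a deviation of exactly the threshold stays neutral
  tol <- 1e-12
  ifelse(tcn - base_ploidy - threshold > tol, "gain",
         ifelse(base_ploidy - tcn - threshold > tol, "loss", "neutral"))
}

#' Call loss of heterozygosity on segments
#'
#' LOH when the minor-allele copy number is known and below 0.5 (rounds
#' to zero copies of one allele); NA when the minor copy number is
#' missing.
#'
#' @param minor_cn minor-allele copy number (vector, may contain NA).
#' @return logical vector with NA for unknown.
#' @export
call_loh <- function(minor_cn) {
  ifelse(is.na(minor_cn), NA, minor_cn < 0.5)
}

#' Annotate segments of one or more samples with state and LOH
#'
#' @param segments a \code{cn_segments} table.
#' @param ploidies named vector of base ploidies per sample_id.
#' @param threshold deviation threshold (default 0.7).
#' @return segments with \code{state} and \code{loh} columns; samples
#'   without a ploidy are dropped with a warning.
#' @export
annotate_cna_states <- function(segments, ploidies, threshold = 0.7) {
  known <- segments$sample_id %in% names(ploidies)
  if (any(!known)) {
    warning("dropping sample(s) without ploidy: ",
            paste(unique(segments$sample_id[!known]), collapse = ", "))
    segments <- segments[known, , drop = FALSE]
  }
  segments$state <- NA_character_
  for (s in unique(segments$sample_id)) {
    i <- segments$sample_id == s
    segments$state[i] <- call_cna_state(segments$tcn[i],
                                        ploidies[[s]], threshold)
  }
  segments$loh <- call_loh(segments$minor_cn)
  segments
}

#' Arm-level recurrence of gains, losses and LOH across a cohort
#'
#' For each chromosome arm, the proportion of samples carrying at least
#' one gain (resp. loss, LOH) segment overlapping the arm by at least
#' 1 bp. The denominator for an arm is the number of samples with any
#' segment data on that chromosome. Segments spanning the centromere
#' count for both arms. Sex chromosomes are excluded by default.
#'
#' @param segments annotated segments (see
#'   \code{\link{annotate_cna_states}}).
#' @param arms an \code{arm_map}.
#' @param include_sex include X/Y arms (default FALSE).
#' @return data.frame per arm: chrom, arm, n_samples, gain, loss, loh
#'   proportions.
#' @export
arm_recurrence <- function(segments, arms, include_sex = FALSE) {
  stopifnot(all(c("state", "loh") %in% names(segments)))
  if (!include_sex)
    arms <- arms[!arms$chrom %in% c("X", "Y"), , drop = FALSE]
  out <- lapply(seq_len(nrow(arms)), function(i) {
    a <- arms[i, ]
    on_chrom <- segments[segments$chrom == a$chrom, , drop = FALSE]
    denom <- length(unique(on_chrom$sample_id))
    ov <- on_chrom[on_chrom$start <= a$end & on_chrom$end >= a$start, ,
                   drop = FALSE]
    prop <- function(flag) {
      if (denom == 0) return(0)
      length(unique(ov$sample_id[flag])) / denom
    }
    data.frame(chrom = a$chrom, arm = a$arm, n_samples = denom,
               gain = prop(ov$state == "gain"),
               loss = prop(ov$state == "loss"),
               loh = prop(ov$loh %in% TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-gene copy-number state per sample
#'
#' A gene inherits the state of every overlapping non-neutral segment;
#' genes overlapped by both gain and loss segments in the same sample are
#' reported as "complex"; genes overlapping only neutral segments are
#' neutral.
#'
#' @param segments annotated segments.
#' @param models a \code{gene_model_set}.
#' @return data.frame sample_id, gene_id, state, loh.
#' @export
annotate_genes_cna <- function(segments, models) {
  m <- as.data.frame(models)
  gene_span <- do.call(rbind, lapply(
    split(m, paste(m$chrom, m$gene_id)), function(g)
      data.frame(chrom = g$chrom[1], gene_id = g$gene_id[1],
                 start = min(g$start), end = max(g$end),
                 stringsAsFactors = FALSE)))
  out <- list()
  for (s in unique(segments$sample_id)) {
    seg <- segments[segments$sample_id == s, , drop = FALSE]
    for (i in seq_len(nrow(gene_span))) {
      g <- gene_span[i, ]
      ov <- seg[seg$chrom == g$chrom & seg$start <= g$end &
                  seg$end >= g$start, , drop = FALSE]
      if (nrow(ov) == 0) next
      states <- unique(ov$state)
      state <- if (all(c("gain", "loss") %in% states)) "complex"
        else if ("gain" %in% states) "gain"
        else if ("loss" %in% states) "loss"
        else "neutral"
      out[[length(out) + 1L]] <- data.frame(
        sample_id = s, gene_id = g$gene_id, state = state,
        loh = any(ov$loh %in% TRUE), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(sample_id = character(), gene_id = character(),
                      state = character(), loh = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
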