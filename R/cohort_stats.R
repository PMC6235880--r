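MUTATION_CHANNELS <- c("coding_nonsilent", "ncRNA", "UTR3")

#' Build a gene x sample binary mutation matrix
#'
#' One matrix per analysis channel: coding_nonsilent (non-silent CDS and
#' splice-site mutations), ncRNA (exonic mutations on non-coding genes),
#' or UTR3 (3'-UTR mutations, kept as their own channel). Multiple
#' mutations of a gene in a sample collapse to a single 1.
#'
#' @param annotated data.frame of annotated variants across the cohort,
#'   with sample_id, gene_ids, region_class and non_silent columns.
#' @param channel one of \code{"coding_nonsilent"}, \code{"ncRNA"},
#'   \code{"UTR3"}.
#' @param samples optional character vector fixing the sample (column)
#'   set, so samples without qualifying mutations keep a zero column.
#' @return binary matrix, genes in rows, samples in columns.
#' @export
build_mutation_matrix <- function(annotated, channel, samples = NULL) {
  if (!channel %in% MUTATION_CHANNELS)
    stop("unknown channel: ", channel)
  keep <- switch(channel,
    coding_nonsilent = annotated$region_class %in% c("CDS", "splice_site") &
      annotated$non_silent,
    ncRNA = annotated$region_class == "ncRNA_exon",
    UTR3 = annotated$region_class == "UTR3")
  hits <- annotated[keep & annotated$gene_ids != "", , drop = FALSE]
  if (is.null(samples)) samples <- sort(unique(annotated$sample_id))
  if (nrow(hits) == 0 || length(samples) == 0)
    return(matrix(0L, 0, length(samples),
                  dimnames = list(NULL, samples)))
  long <- do.call(rbind, lapply(seq_len(nrow(hits)), function(i) {
    data.frame(gene = strsplit(hits$gene_ids[i], ",", fixed = TRUE)[[1]],
               sample = hits$sample_id[i], stringsAsFactors = FALSE)
  }))
  genes <- sort(unique(long$gene))
  mat <- matrix(0L, length(genes), length(samples),
                dimnames = list(genes, samples))
  mat[cbind(match(long$gene, genes), match(long$sample, samples))] <- 1L
  mat
}

#' Recurrently mutated genes
#'
#' Genes mutated in at least min_samples samples, sorted by descending
#' count, ties broken alphabetically.
#'
#' @param matrix binary gene x sample matrix.
#' @param min_samples recurrence cutoff (>= 1; the cohort analyses use 4,
#'   i.e. 17% of 24 samples).
#' @return data.frame gene, n_samples.
#' @export
recurrent_genes <- function(matrix, min_samples = 4) {
  stopifnot(min_samples >= 1)
  counts <- rowSums(matrix)
  keep <- counts >= min_samples
  out <- data.frame(gene = as.character(rownames(matrix)[keep]),
                    n_samples = as.integer(counts[keep]),
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0) return(out)
  out <- out[order(-out$n_samples, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mutual exclusivity of a gene pair
#'
#' A pair is mutually exclusive when no more than max_overlap samples
#' (default 1) carry mutations in both genes. The two-sided Fisher exact
#' p-value of the 2x2 presence table and the direction of association
#' (odds ratio above/below 1) are reported alongside.
#'
#' @param matrix binary gene x sample matrix.
#' @param geneA,geneB row names of the two genes.
#' @param max_overlap exclusivity threshold (default 1).
#' @return list with overlap, exclusive, fisher_p, odds_direction.
#' @export
mutual_exclusivity <- function(matrix, geneA, geneB, max_overlap = 1) {
  for (g in c(geneA, geneB))
    if (!g %in% rownames(matrix)) stop("gene not in matrix: ", g)
  a <- matrix[geneA, ] > 0
  b <- matrix[geneB, ] > 0
  tab <- base::matrix(c(sum(a & b), sum(a & !b),
                        sum(!a & b), sum(!a & !b)), 2, 2)
  p <- fisher_exact_2x2(tab)
  or_dir <- if (tab[1, 1] * tab[2, 2] > tab[1, 2] * tab[2, 1])
    "co-occurrence" else "exclusivity"
  list(overlap = sum(a & b), exclusive = sum(a & b) <= max_overlap,
       fisher_p = p, odds_direction = or_dir)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p by the probability-mass rule: the sum of
#' hypergeometric probabilities, over all tables with the observed
#' margins, that do not exceed the observed table's probability (within
#' 1e-12 relative tolerance). Any zero margin gives p = 1 by convention.
#'
#' @param table 2x2 non-negative integer matrix.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == round(table)))
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ])
  c1 <- sum(table[, 1]); c2 <- sum(table[, 2])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  n <- r1 + r2
  k_range <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(k_range, r1, r2, c1)
  p_obs <- stats::dhyper(table[1, 1], r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction, df = 1. Errors when an expected count
#' is zero (use the Fisher test instead).
#'
#' @param table 2x2 non-negative matrix.
#' @return list with statistic and p.
#' @export
chi2_test_2x2 <- function(table) {
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  n <- sum(table)
  expected <- outer(rowSums(table), colSums(table)) / n
  if (any(expected == 0))
    stop("zero expected count; use fisher_exact_2x2")
  stat <- sum((table - expected)^2 / expected)
  list(statistic = stat, p = stats::pchisq(stat, df = 1,
                                           lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control: q_(i) = min_{j >= i} m p_(j) / j, capped at 1,
#' returned in the input order.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return adjusted q-values.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Upper-tail hypergeometric enrichment
#'
#' Probability of observing at least the seen number of hits of a gene
#' set among the hit genes, drawing without replacement from the
#' universe — the classic gene-set enrichment test (apply
#' \code{\link{bh_adjust}} across many sets).
#'
#' @param hit_set character vector of hit genes.
#' @param gene_set character vector, the annotated set.
#' @param universe character vector containing both.
#' @return upper-tail p-value.
#' @export
hypergeometric_enrichment <- function(hit_set, gene_set, universe) {
  if (!all(hit_set %in% universe) || !all(gene_set %in% universe))
    stop("hit_set and gene_set must be subsets of the universe")
  k <- length(intersect(hit_set, gene_set))
  stats::phyper(k - 1, length(gene_set),
                length(universe) - length(gene_set),
                length(hit_set), lower.tail = FALSE)
}
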