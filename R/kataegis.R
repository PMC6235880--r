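#' Inter-mutation distances per chromosome
#'
#' Distance of each mutation to its predecessor on the same chromosome;
#' the first mutation of a chromosome has no distance (NA). Duplicate
#' positions yield distance 0. Unsorted input is sorted with a warning.
#'
#' @param positions data.frame with chrom and pos.
#' @return the sorted positions with a \code{distance} column.
#' @export
intermutation_distances <- function(positions) {
  stopifnot(all(c("chrom", "pos") %in% names(positions)))
  out <- NULL
  for (ch in unique(positions$chrom)) {
    p <- positions$pos[positions$chrom == ch]
    if (is.unsorted(p)) {
      warning("positions on chromosome ", ch, " unsorted; sorting")
      p <- sort(p)
    }
    out <- rbind(out, data.frame(
      chrom = ch, pos = p, distance = c(NA, diff(p)),
      stringsAsFactors = FALSE))
  }
  out
}

#' Detect kataegis loci
#'
#' A kataegis locus is a cluster of at least k mutations within a window
#' (default 5 mutations within 10 kb, span measured last minus first,
#' inclusive). Every run of k consecutive mutations spanning <= window
#' seeds a locus; overlapping or adjacent qualifying runs are merged into
#' maximal loci whose members are all mutations inside the merged span.
#'
#' @param positions data.frame with chrom and pos (one sample's SNVs).
#' @param k minimum cluster size (>= 2).
#' @param window maximum span in bp (>= 1).
#' @return data.frame of loci: chrom, start, end, size; plus a
#'   \code{members} list-column of member positions.
#' @export
detect_kataegis <- function(positions, k = 5, window = 10000) {
  stopifnot(k >= 2, window >= 1)
  loci <- list()
  for (ch in unique(positions$chrom)) {
    p <- sort(positions$pos[positions$chrom == ch])
    n <- length(p)
    if (n < k) next
    starts <- seq_len(n - k + 1)
    qual <- starts[p[starts + k - 1] - p[starts] <= window]
    if (length(qual) == 0) next
    covered <- sort(unique(unlist(lapply(qual, function(i) i:(i + k - 1)))))
    # maximal runs of consecutive covered indices
    brk <- c(0, which(diff(covered) > 1), length(covered))
    for (b in seq_len(length(brk) - 1)) {
      idx <- covered[(brk[b] + 1):brk[b + 1]]
      loci[[length(loci) + 1L]] <- data.frame(
        chrom = ch, start = p[idx[1]], end = p[idx[length(idx)]],
        size = length(idx), stringsAsFactors = FALSE)
      loci[[length(loci)]]$members <- list(p[idx])
    }
  }
  if (length(loci) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), size = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, loci)
  rownames(out) <- NULL
  out
}

#' Annotate kataegis loci with proximal genes
#'
#' A gene is proximal to a locus when the minimum distance between the
#' locus span and the gene span (aggregated over the gene's intervals) is
#' at most max_dist; overlap counts as distance 0 and the boundary is
#' inclusive.
#'
#' @param loci locus table from \code{\link{detect_kataegis}}.
#' @param models a \code{gene_model_set}.
#' @param max_dist proximity threshold in bp (default 10 kb).
#' @return loci with a \code{proximal_genes} column (comma-joined).
#' @export
annotate_locus_proximity <- function(loci, models, max_dist = 10000) {
  if (nrow(loci) == 0) {
    loci$proximal_genes <- character(0)
    return(loci)
  }
  m <- as.data.frame(models)
  gene_span <- do.call(rbind, lapply(
    split(m, paste(m$chrom, m$gene_id)), function(g)
      data.frame(chrom = g$chrom[1], gene_id = g$gene_id[1],
                 start = min(g$start), end = max(g$end),
                 stringsAsFactors = FALSE)))
  loci$proximal_genes <- vapply(seq_len(nrow(loci)), function(i) {
    g <- gene_span[gene_span$chrom == loci$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) return("")
    gap <- pmax(0, pmax(g$start - loci$end[i], loci$start[i] - g$end))
    paste(sort(unique(g$gene_id[gap <= max_dist])), collapse = ",")
  }, character(1))
  loci
}

#' Recurrent kataegis regions across samples
#'
#' Intersects per-sample kataegis loci and reports genomic regions where
#' loci from at least min_samples distinct samples overlap.
#'
#' @param loci_by_sample named list of per-sample locus tables.
#' @param min_samples recurrence threshold (default 2).
#' @return data.frame of recurrent regions with supporting sample counts.
#' @export
recurrent_kataegis_regions <- function(loci_by_sample, min_samples = 2) {
  all_loci <- do.call(rbind, lapply(names(loci_by_sample), function(s) {
    l <- loci_by_sample[[s]]
    if (nrow(l) == 0) return(NULL)
    data.frame(sample_id = s, chrom = l$chrom, start = l$start,
               end = l$end, stringsAsFactors = FALSE)
  }))
  out <- list()
  if (!is.null(all_loci)) {
    for (ch in unique(all_loci$chrom)) {
      l <- all_loci[all_loci$chrom == ch, , drop = FALSE]
      ir <- IRanges::reduce(IRanges::IRanges(l$start, l$end))
      ov <- IRanges::findOverlaps(ir, IRanges::IRanges(l$start, l$end))
      for (i in seq_along(ir)) {
        samples <- unique(l$sample_id[S4Vectors::subjectHits(ov)[
          S4Vectors::queryHits(ov) == i]])
        if (length(samples) >= min_samples)
          out[[length(out) + 1L]] <- data.frame(
            chrom = ch, start = IRanges::start(ir)[i],
            end = IRanges::end(ir)[i], n_samples = length(samples),
            samples = paste(sort(samples), collapse = ","),
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_samples = integer(),
                      samples = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
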