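#' Construct a 96-context catalog from counts
#'
#' @param counts named numeric vector over the 96 canonical context
#'   labels (any order); missing labels are taken as 0.
#' @return a \code{catalog96}: named counts in canonical order.
#' @export
as_catalog96 <- function(counts) {
  canon <- context_labels_96()
  out <- stats::setNames(numeric(96), canon)
  if (length(counts)) {
    bad <- setdiff(names(counts), canon)
    if (length(bad)) stop("unknown context label(s): ",
                          paste(utils::head(bad, 3), collapse = ", "))
    if (any(counts < 0)) stop("negative catalog counts")
    out[names(counts)] <- counts
  }
  structure(out, class = "catalog96")
}

#' Total mutations in a catalog
#' @param catalog a \code{catalog96}.
#' @return numeric total.
#' @export
catalog_total <- function(catalog) sum(unclass(catalog))

#' Build a 96-context catalog from SNVs with contexts
#'
#' Purine-reference SNVs are reverse-complemented into the
#' pyrimidine-centered convention. SNVs whose context contains N (or is
#' inconsistent with the reference base) are skipped and reported in the
#' \code{skipped} attribute.
#'
#' @param snvs data.frame with ref, alt, context columns (single-base
#'   alleles; rows with longer alleles are ignored as non-SNVs).
#' @return a \code{catalog96} whose total equals the number of usable
#'   SNVs; attribute \code{skipped} counts the rejected ones.
#' @export
build_catalog <- function(snvs) {
  snv <- snvs[nchar(snvs$ref) == 1L & nchar(snvs$alt) == 1L, , drop = FALSE]
  if (nrow(snv) == 0) return(as_catalog96(numeric()))
  labels <- context_label(snv$ref, snv$alt, snv$context)
  skipped <- sum(is.na(labels))
  tab <- table(labels[!is.na(labels)])
  out <- as_catalog96(stats::setNames(as.numeric(tab), names(tab)))
  attr(out, "skipped") <- skipped
  out
}

#' Decompose a catalog against a signature matrix by NNLS
#'
#' Fits absolute exposures e = argmin_{e >= 0} ||C - W e||_2, in
#' mutation-count units, and reports normalized exposures e / sum(e) and
#' the residual norm.
#'
#' @param catalog a \code{catalog96} with positive total.
#' @param W a \code{signature_matrix}.
#' @return an \code{exposure_vector}: list with signature_ids, exposure
#'   (absolute), normalized, and residual.
#' @export
nnls_decompose <- function(catalog, W) {
  stopifnot(inherits(W, "signature_matrix"))
  C <- unclass(as_catalog96(stats::setNames(as.numeric(catalog),
                                            names(catalog))))
  if (sum(C) == 0)
    stop("catalog is empty; skip this sample/stratum")
  fit <- nnls_fit(W$W, C)
  e <- stats::setNames(fit$x, W$signature_ids)
  norm <- if (sum(e) > 0) e / sum(e) else e
  structure(list(signature_ids = W$signature_ids, exposure = e,
                 normalized = norm, residual = fit$residual),
            class = "exposure_vector")
}

#' @export
print.exposure_vector <- function(x, ...) {
  cat("Signature exposures (", sum(x$exposure > 0), " active, residual ",
      format(x$residual, digits = 4), ")\n", sep = "")
  print(round(x$normalized[x$exposure > 0], 4))
  invisible(x)
}

.expand_cutoffs <- function(cutoffs, signature_ids) {
  if (length(cutoffs) == 1 && is.null(names(cutoffs)))
    return(stats::setNames(rep(cutoffs, length(signature_ids)),
                           signature_ids))
  out <- stats::setNames(numeric(length(signature_ids)), signature_ids)
  out[names(cutoffs)] <- cutoffs
  out
}

#' Apply signature-specific cutoffs to an NNLS fit
#'
#' Signatures whose normalized exposure falls below their cutoff are
#' removed and the NNLS is re-run on the remaining columns, iterating
#' until every surviving signature meets its cutoff. With all cutoffs 0
#' the fit is returned unchanged.
#'
#' @param catalog a \code{catalog96}.
#' @param W a \code{signature_matrix}.
#' @param cutoffs scalar or per-signature named vector of thresholds on
#'   normalized exposure (default 0.06 for every signature).
#' @return an \code{exposure_vector} over all of W's signatures, with
#'   zeros for removed ones; if no signature survives, a zero vector with
#'   a warning.
#' @export
apply_signature_cutoffs <- function(catalog, W, cutoffs = 0.06) {
  cut <- .expand_cutoffs(cutoffs, W$signature_ids)
  active <- W$signature_ids
  repeat {
    if (length(active) == 0) {
      warning("all signatures removed by cutoffs")
      zero <- stats::setNames(numeric(length(W$signature_ids)),
                              W$signature_ids)
      return(structure(list(signature_ids = W$signature_ids,
                            exposure = zero, normalized = zero,
                            residual = sqrt(sum(as.numeric(catalog)^2))),
                       class = "exposure_vector"))
    }
    Wsub <- structure(list(contexts = W$contexts, signature_ids = active,
                           W = W$W[, active, drop = FALSE]),
                      class = "signature_matrix")
    fit <- nnls_decompose(catalog, Wsub)
    below <- active[fit$normalized < cut[active]]
    if (length(below) == 0) break
    active <- setdiff(active, below)
  }
  e <- stats::setNames(numeric(length(W$signature_ids)), W$signature_ids)
  e[active] <- fit$exposure
  norm <- if (sum(e) > 0) e / sum(e) else e
  structure(list(signature_ids = W$signature_ids, exposure = e,
                 normalized = norm, residual = fit$residual),
            class = "exposure_vector")
}

#' Cohort-level signature detection
#'
#' Sums the given catalogs, fits the pooled catalog with cutoffs, and
#' returns the surviving signatures — the restricted signature set to be
#' used for all per-sample and per-stratum fits.
#'
#' @param catalogs list of \code{catalog96}.
#' @param W a \code{signature_matrix}.
#' @param cutoffs as in \code{\link{apply_signature_cutoffs}}.
#' @return character vector of detected signature IDs.
#' @export
cohort_signature_detection <- function(catalogs, W, cutoffs = 0.06) {
  if (length(catalogs) == 0) stop("empty cohort")
  pooled <- as_catalog96(stats::setNames(
    Reduce(`+`, lapply(catalogs, as.numeric)), context_labels_96()))
  fit <- suppressWarnings(apply_signature_cutoffs(pooled, W, cutoffs))
  active <- fit$signature_ids[fit$exposure > 0]
  if (length(active) == 0)
    stop("no signature detected at cohort level under the given cutoffs")
  active
}

#' Restrict a signature matrix to a set of signatures
#' @param W a \code{signature_matrix}.
#' @param ids signature IDs to keep.
#' @return the restricted \code{signature_matrix}.
#' @export
restrict_signatures <- function(W, ids) {
  stopifnot(all(ids %in% W$signature_ids))
  structure(list(contexts = W$contexts, signature_ids = ids,
                 W = W$W[, ids, drop = FALSE]),
            class = "signature_matrix")
}

.paired_wilcox_p <- function(x, y) {
  d <- x - y
  if (all(d == 0)) return(1)
  suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE,
                       exact = length(d) <= 25)$p.value)
}

#' Compare normalized exposures between strata across patients
#'
#' For each signature and each pair of strata, a two-sided paired
#' Wilcoxon signed-rank test across patients (exact distribution for
#' n <= 25), with Benjamini-Hochberg correction across signatures within
#' each strata pair, and the median paired difference as direction.
#'
#' @param exposures named list of matrices (one per stratum, e.g.
#'   \code{shared}, \code{tumor_private}, \code{met_private}), each
#'   patients x signatures with identical dimnames.
#' @return data.frame with columns pair, signature, median_diff, p, q.
#' @export
compare_strata_exposures <- function(exposures) {
  stopifnot(is.list(exposures), length(exposures) >= 2)
  dims <- lapply(exposures, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("stratum exposure matrices must share dimensions")
  if (nrow(exposures[[1]]) < 3)
    stop("need at least 3 patients for strata comparison")
  sigs <- colnames(exposures[[1]])
  pairs <- utils::combn(names(exposures), 2, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    a <- exposures[[pr[1]]]
    b <- exposures[[pr[2]]]
    p <- vapply(sigs, function(s) .paired_wilcox_p(a[, s], b[, s]),
                numeric(1))
    data.frame(pair = paste(pr[1], "vs", pr[2]), signature = sigs,
               median_diff = vapply(sigs, function(s)
                 stats::median(a[, s] - b[, s]), numeric(1)),
               p = p, q = bh_adjust(p), stringsAsFactors = FALSE,
               row.names = NULL)
  }))
  out
}

#' Unsupervised clustering of exposure profiles
#'
#' Hierarchical agglomerative clustering of rows (samples or strata) with
#' Euclidean distance and complete linkage; deterministic for a fixed
#' input (ties resolved by row index order).
#'
#' @param mat numeric matrix, rows = samples, columns = signatures.
#' @return list with the \code{hclust} tree and the leaf \code{order}.
#' @export
cluster_exposures <- function(mat) {
  if (nrow(mat) < 2) stop("need at least 2 rows to cluster")
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "complete")
  list(tree = hc, order = hc$order)
}

#' Associate signature exposures with a binary sample covariate
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per signature between
#' the two groups (e.g. diploid vs aneuploid samples), exact for small n,
#' with BH correction across signatures.
#'
#' @param mat numeric matrix, rows = samples, columns = signatures.
#' @param group logical or two-level factor over rows.
#' @return data.frame with signature, median difference
#'   (group TRUE/first level minus other), p and q.
#' @export
associate_exposure_with_group <- function(mat, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2 || any(table(group) == 0))
    stop("group must have two non-empty levels")
  g1 <- group == levels(group)[1]
  p <- vapply(colnames(mat), function(s) {
    suppressWarnings(
      stats::wilcox.test(mat[g1, s], mat[!g1, s],
                         exact = nrow(mat) <= 50)$p.value)
  }, numeric(1))
  data.frame(signature = colnames(mat),
             median_diff = apply(mat[g1, , drop = FALSE], 2, stats::median) -
               apply(mat[!g1, , drop = FALSE], 2, stats::median),
             p = p, q = bh_adjust(p), stringsAsFactors = FALSE,
             row.names = NULL)
}
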