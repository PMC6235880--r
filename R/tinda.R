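#' Build BAF points for tumor-in-normal detection
#'
#' One point per retained mutated position of the tumor/metastasis pair:
#' the control (matched normal) B-allele frequency against the BAF of the
#' chosen sample (tumor or metastasis), together with the underlying read
#' counts. Positions in the supplied common-variant set are filtered out,
#' and positions without control coverage are dropped with a message.
#'
#' @param trio a \code{trio_dataset}.
#' @param sample \code{"tumor"} or \code{"met"}: which sample's BAF to
#'   pair with the control.
#' @param common_positions character vector of "chrom:pos" keys of known
#'   common variants (default: the set carried by the trio).
#' @return data.frame of BAF points with variant keys, read counts and
#'   the original somatic/germline label.
#' @export
build_baf_points <- function(trio, sample = c("tumor", "met"),
                             common_positions = trio$common_positions) {
  sample <- match.arg(sample)
  calls <- trio$calls
  empty <- data.frame(chrom = character(), pos = numeric(),
                      ref = character(), alt = character(),
                      control_baf = numeric(), sample_baf = numeric(),
                      control_alt = integer(), control_depth = integer(),
                      sample_alt = integer(), sample_depth = integer(),
                      original_label = character(),
                      stringsAsFactors = FALSE)
  if (nrow(calls) == 0) return(empty)
  key <- paste0(calls$chrom, ":", calls$pos)
  calls <- calls[!key %in% common_positions, , drop = FALSE]
  control_depth <- calls$normal_ref + calls$normal_alt
  dropped <- sum(control_depth == 0)
  if (dropped > 0)
    message(dropped, " position(s) without control coverage dropped")
  calls <- calls[control_depth > 0, , drop = FALSE]
  if (nrow(calls) == 0) return(empty)
  s_alt <- calls[[paste0(sample, "_alt")]]
  s_depth <- s_alt + calls[[paste0(sample, "_ref")]]
  data.frame(
    chrom = calls$chrom, pos = calls$pos, ref = calls$ref, alt = calls$alt,
    control_baf = .sample_maf(calls, "normal"),
    sample_baf = ifelse(s_depth > 0, s_alt / s_depth, 0),
    control_alt = calls$normal_alt,
    control_depth = calls$normal_ref + calls$normal_alt,
    sample_alt = s_alt, sample_depth = s_depth,
    original_label = ifelse(calls$germline, "germline", "somatic"),
    stringsAsFactors = FALSE)
}

kmeanspp_centers <- function(X, k) {
  U <- unique(X)
  if (nrow(U) < k) k <- nrow(U)
  centers <- matrix(NA_real_, k, ncol(X))
  i <- sample.int(nrow(U), 1)
  centers[1, ] <- U[i, ]
  if (k > 1) {
    d2 <- rowSums(sweep(U, 2, centers[1, ])^2)
    for (j in 2:k) {
      i <- if (all(d2 == 0)) sample.int(nrow(U), 1) else
        sample.int(nrow(U), 1, prob = d2)
      centers[j, ] <- U[i, ]
      d2 <- pmin(d2, rowSums(sweep(U, 2, centers[j, ])^2))
    }
  }
  centers
}

#' Cluster BAF points by a binomial mixture model
#'
#' Single-pass EM for a k-component mixture (default k = 9, no model
#' selection): each component c has a control-BAF mean and a sample-BAF
#' mean, and a point's likelihood under c is the product of the two
#' binomial likelihoods of its alt counts. Component means are seeded by
#' k-means++ on the BAF plane; 100 EM iterations; points are then hard-
#' assigned to the maximum-responsibility component. Deterministic for a
#' fixed seed. The binomial mixture is chosen over a hard spatial
#' partition because overlapping components share a homogeneous cloud
#' (such as the germline heterozygous blob at BAF 0.5/0.5) instead of
#' slicing it, which keeps the identity-line rule meaningful.
#'
#' If fewer distinct points than k are available, k is reduced with a
#' warning. Points lacking read-count columns are assumed to have the
#' given default depth.
#'
#' @param points BAF points from \code{\link{build_baf_points}}.
#' @param k number of mixture components (default 9).
#' @param seed RNG seed.
#' @param iter EM iterations (default 100).
#' @param default_depth depth substituted when count columns are absent.
#' @return integer cluster assignment per point.
#' @export
cluster_baf_pairs <- function(points, k = 9, seed = 1, iter = 100,
                              default_depth = 36) {
  n <- nrow(points)
  if (n == 0) return(integer())
  if (!all(c("control_alt", "control_depth", "sample_alt",
             "sample_depth") %in% names(points))) {
    points$control_depth <- default_depth
    points$control_alt <- round(points$control_baf * default_depth)
    points$sample_depth <- default_depth
    points$sample_alt <- round(points$sample_baf * default_depth)
  }
  # canonical point order makes the result invariant to input order
  ord <- order(points$control_baf, points$sample_baf, points$control_alt,
               points$control_depth, points$sample_alt, points$sample_depth)
  points <- points[ord, , drop = FALSE]
  X <- cbind(points$control_baf, points$sample_baf)
  set.seed(seed)
  n_distinct <- nrow(unique(X))
  if (n_distinct < k) {
    warning("fewer distinct points (", n_distinct, ") than k = ", k,
            "; reducing k")
    k <- n_distinct
  }
  if (k == 1) return(rep(1L, n))
  centers <- kmeanspp_centers(X, k)
  eps <- 1e-4
  p_c <- pmin(pmax(centers[, 1], eps), 1 - eps)   # control means
  p_s <- pmin(pmax(centers[, 2], eps), 1 - eps)   # sample means
  w <- rep(1 / k, k)
  ll <- matrix(0, n, k)
  for (it in seq_len(iter)) {
    for (c in seq_len(k)) {
      ll[, c] <- log(w[c]) +
        stats::dbinom(points$control_alt, points$control_depth, p_c[c],
                      log = TRUE) +
        stats::dbinom(points$sample_alt, points$sample_depth, p_s[c],
                      log = TRUE)
    }
    m <- apply(ll, 1, max)
    r <- exp(ll - m)
    r <- r / rowSums(r)
    nk <- colSums(r)
    keep <- nk > 1e-12
    p_c[keep] <- pmin(pmax(
      colSums(r[, keep, drop = FALSE] * points$control_alt) /
        colSums(r[, keep, drop = FALSE] * points$control_depth),
      eps), 1 - eps)
    p_s[keep] <- pmin(pmax(
      colSums(r[, keep, drop = FALSE] * points$sample_alt) /
        colSums(r[, keep, drop = FALSE] * points$sample_depth),
      eps), 1 - eps)
    w <- pmax(nk / n, 1e-12)
    w <- w / sum(w)
  }

  # Binomial mixtures with coinciding means are not identifiable: EM can
  # leave a homogeneous cloud split across near-duplicate components whose
  # hard assignments then slice pure noise into spatial halves. Merge
  # components whenever collapsing a pair costs less likelihood than the
  # 3 parameters it frees (BIC), so only genuinely distinct clusters
  # survive.
  logsumexp_rows <- function(m) {
    mx <- apply(m, 1, max)
    mx + log(rowSums(exp(m - mx)))
  }
  comp_ll <- function(pc, ps, wc) {
    log(wc) +
      stats::dbinom(points$control_alt, points$control_depth, pc,
                    log = TRUE) +
      stats::dbinom(points$sample_alt, points$sample_depth, ps, log = TRUE)
  }
  repeat {
    k_cur <- length(w)
    if (k_cur == 1) break
    for (c in seq_len(k_cur)) ll[, c] <- comp_ll(p_c[c], p_s[c], w[c])
    ll <- ll[, seq_len(k_cur), drop = FALSE]
    L <- sum(logsumexp_rows(ll))
    r <- exp(ll - logsumexp_rows(ll))
    best <- NULL
    best_score <- Inf
    for (a in seq_len(k_cur - 1)) for (b in (a + 1):k_cur) {
      rm <- r[, a] + r[, b]
      pc <- min(max(sum(rm * points$control_alt) /
                      sum(rm * points$control_depth), eps), 1 - eps)
      ps <- min(max(sum(rm * points$sample_alt) /
                      sum(rm * points$sample_depth), eps), 1 - eps)
      ll_m <- cbind(ll[, -c(a, b), drop = FALSE],
                    comp_ll(pc, ps, w[a] + w[b]))
      score <- 2 * (L - sum(logsumexp_rows(ll_m)))
      if (score < best_score) {
        best_score <- score
        best <- list(a = a, b = b, pc = pc, ps = ps)
      }
    }
    if (is.null(best) || best_score >= 3 * log(n)) break
    p_c <- c(p_c[-c(best$a, best$b)], best$pc)
    p_s <- c(p_s[-c(best$a, best$b)], best$ps)
    w <- c(w[-c(best$a, best$b)], w[best$a] + w[best$b])
    ll <- matrix(0, n, length(w))
  }
  for (c in seq_along(w)) ll[, c] <- comp_ll(p_c[c], p_s[c], w[c])
  asg <- as.integer(apply(ll[, seq_along(w), drop = FALSE], 1, which.max))
  out <- integer(n)
  out[ord] <- asg
  out
}

#' Classify clusters as tumor-in-normal and collect rescues
#'
#' A cluster is tumor-in-normal iff (i) at least 75% of its points lie
#' strictly above the identity line (sample BAF > control BAF), (ii) its
#' centroid sample MAF exceeds 1%, and (iii) its centroid control MAF is
#' below 45%. Germline-labelled members of qualifying clusters are
#' rescued; somatic-labelled calls are never demoted.
#'
#' @param points BAF points.
#' @param assignments integer cluster ids from
#'   \code{\link{cluster_baf_pairs}}.
#' @param above_frac,maf_min,control_max the three cluster rules
#'   (defaults 0.75, 0.01, 0.45).
#' @return a \code{tinda_result}: per-cluster statistics and the rescued
#'   variant keys.
#' @export
classify_clusters <- function(points, assignments, above_frac = 0.75,
                              maf_min = 0.01, control_max = 0.45) {
  stopifnot(nrow(points) == length(assignments))
  if (length(assignments) == 0) {
    return(structure(list(
      clusters = data.frame(cluster = integer(), size = integer(),
                            frac_above = numeric(),
                            centroid_sample = numeric(),
                            centroid_control = numeric(),
                            tumor_in_normal = logical()),
      rescued = character(), assignments = integer()),
      class = "tinda_result"))
  }
  ids <- sort(unique(assignments))
  stats_df <- do.call(rbind, lapply(ids, function(cl) {
    m <- points[assignments == cl, , drop = FALSE]
    data.frame(
      cluster = cl, size = nrow(m),
      frac_above = mean(m$sample_baf > m$control_baf),
      centroid_sample = mean(m$sample_baf),
      centroid_control = mean(m$control_baf),
      stringsAsFactors = FALSE)
  }))
  stats_df$tumor_in_normal <- stats_df$frac_above >= above_frac &
    stats_df$centroid_sample > maf_min &
    stats_df$centroid_control < control_max
  tin <- stats_df$cluster[stats_df$tumor_in_normal]
  member <- assignments %in% tin & points$original_label == "germline"
  rescued <- paste0(points$chrom, ":", points$pos, ":", points$ref, ":",
                    points$alt)[member]
  structure(list(clusters = stats_df, rescued = rescued,
                 assignments = assignments),
            class = "tinda_result")
}

#' Apply tumor-in-normal rescue to a trio
#'
#' For each of the tumor and the metastasis, builds BAF points against
#' the control (excluding common variants), clusters them with the
#' binomial-mixture EM, and applies the tumor-in-normal cluster rules.
#' A germline-labelled variant rescued in either run is reclassified as
#' somatic: the caller-somatic flag is set in each sample of the pair
#' where the variant has read support and the germline label is cleared,
#' so rescued variants enter stratification. An audit table records
#' every reclassification.
#'
#' @param trio a \code{trio_dataset}.
#' @param common_positions known common-variant "chrom:pos" keys.
#' @param k number of clusters (default 9).
#' @param seed RNG seed.
#' @param ... rule overrides passed to \code{\link{classify_clusters}}.
#' @return list with the modified \code{trio}, \code{result} (per-run
#'   \code{tinda_result}s, elements \code{tumor} and \code{met}) and the
#'   \code{audit} table of reclassified variants.
#' @export
apply_tinda <- function(trio, common_positions = trio$common_positions,
                        k = 9, seed = 1, ...) {
  results <- list()
  rescued <- character()
  for (sample in c("tumor", "met")) {
    points <- build_baf_points(trio, sample, common_positions)
    assignments <- cluster_baf_pairs(points, k = k, seed = seed)
    results[[sample]] <- classify_clusters(points, assignments, ...)
    rescued <- union(rescued, results[[sample]]$rescued)
  }
  key <- paste0(trio$calls$chrom, ":", trio$calls$pos, ":",
                trio$calls$ref, ":", trio$calls$alt)
  hit <- key %in% rescued
  audit <- trio$calls[hit, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  trio$calls$tumor_somatic[hit] <- trio$calls$tumor_somatic[hit] |
    trio$calls$tumor_alt[hit] >= 1
  trio$calls$met_somatic[hit] <- trio$calls$met_somatic[hit] |
    trio$calls$met_alt[hit] >= 1
  trio$calls$germline[hit] <- FALSE
  list(trio = trio, result = results, audit = audit)
}
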