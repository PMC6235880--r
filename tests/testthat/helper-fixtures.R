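# Shared fixtures and independent oracles, built in code at test time.

# small signature matrix with distinguishable profiles
test_signatures <- function(n = 3, seed = 7) {
  synthetic_signature_matrix(n, seed = seed)
}

# a trio whose calls are written directly, for rule-level tests
manual_trio <- function(calls, purity_tumor = 0.6, purity_met = 0.6,
                        ploidy_tumor = 2, ploidy_met = 2,
                        coverage = 36, common = character()) {
  defaults <- data.frame(
    chrom = "1", pos = 1, ref = "C", alt = "T", context = "ACA",
    normal_ref = 30L, normal_alt = 0L, tumor_ref = 30L, tumor_alt = 0L,
    met_ref = 30L, met_alt = 0L, tumor_somatic = FALSE,
    met_somatic = FALSE, germline = FALSE, stringsAsFactors = FALSE)
  for (nm in names(defaults))
    if (!nm %in% names(calls))
      calls[[nm]] <- rep(defaults[[nm]], length.out = nrow(calls))
  structure(list(patient_id = "TEST", calls = calls,
                 purity_tumor = purity_tumor, purity_met = purity_met,
                 ploidy_tumor = ploidy_tumor, ploidy_met = ploidy_met,
                 mean_coverage = coverage, common_positions = common),
            class = "trio_dataset")
}

variant_keys <- function(df) paste(df$chrom, df$pos, df$ref, df$alt)

# truth stratum labels in the vocabulary of stratify_trio
truth_as_stratum <- function(truth) {
  c(truncal = "shared", tumor_private = "tumor_private",
    met_private = "met_private")[truth$stratum]
}

# brute-force kataegis oracle: every contiguous run of >= k sorted
# positions with span <= window marks its members; maximal runs of marked
# members are loci
brute_kataegis <- function(positions, k = 5, window = 10000) {
  out <- list()
  for (ch in unique(positions$chrom)) {
    p <- sort(positions$pos[positions$chrom == ch])
    n <- length(p)
    if (n < k) next
    covered <- rep(FALSE, n)
    for (i in seq_len(n - k + 1)) {
      for (j in (i + k - 1):n) {
        if (p[j] - p[i] <= window) covered[i:j] <- TRUE else break
      }
    }
    idx <- which(covered)
    if (!length(idx)) next
    brk <- c(0, which(diff(idx) > 1), length(idx))
    for (b in seq_len(length(brk) - 1)) {
      m <- idx[(brk[b] + 1):brk[b + 1]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = p[m[1]], end = p[m[length(m)]],
        size = length(m), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), size = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# naive O(n^3) complete-linkage agglomeration oracle: returns sorted merge
# heights
brute_complete_linkage_heights <- function(mat) {
  clusters <- lapply(seq_len(nrow(mat)), identity)
  d <- as.matrix(stats::dist(mat))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        h <- max(d[clusters[[a]], clusters[[b]]])
        if (h < best[1]) best <- c(h, a, b)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  sort(heights)
}

# explicit BH step-up formula, independent of p.adjust
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  ps <- p[o]
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(m * ps[i:m] / (i:m)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# exact paired sign-flip enumeration for the Wilcoxon signed-rank test
# (no ties/zeros assumed)
brute_signed_rank_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  ev <- n * (n + 1) / 4
  vs <- vapply(0:(2^n - 1), function(m) {
    signs <- bitwAnd(m, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, numeric(1))
  mean(abs(vs - ev) >= abs(v_obs - ev) - 1e-9)
}
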