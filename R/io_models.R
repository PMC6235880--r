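REGION_CLASSES <- c("CDS", "UTR5", "UTR3", "ncRNA_exon", "intron",
                    "splice_site")

#' Read gene models from a BED-like file
#'
#' Expects BED columns chrom, start, end, gene_id, score, strand plus a
#' seventh region-class column drawn from the closed vocabulary CDS, UTR5,
#' UTR3, ncRNA_exon, intron, splice_site. On-disk coordinates are 0-based
#' half-open (BED); in memory everything is 1-based inclusive (VCF
#' convention), so start becomes start+1.
#'
#' @param path BED-like file, no header.
#' @return a \code{gene_model_set}: data.frame with columns chrom, start,
#'   end (1-based inclusive), gene_id, strand, region_class.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0 || length(readLines(path, n = 1)) == 0)
    return(as_gene_model_set(empty_gene_models()))
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 7) stop("gene model file needs 7 columns, got ", ncol(df))
  out <- data.frame(
    chrom = normalize_chrom(df[[1]]),
    start = as.numeric(df[[2]]) + 1,   # BED 0-based half-open -> 1-based
    end = as.numeric(df[[3]]),
    gene_id = as.character(df[[4]]),
    strand = as.character(df[[6]]),
    region_class = as.character(df[[7]]),
    stringsAsFactors = FALSE
  )
  as_gene_model_set(out)
}

empty_gene_models <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             gene_id = character(), strand = character(),
             region_class = character(), stringsAsFactors = FALSE)
}

#' Construct a gene model set from 1-based inclusive intervals
#'
#' @param df data.frame with chrom, start, end, gene_id, strand,
#'   region_class (1-based inclusive coordinates).
#' @return validated \code{gene_model_set}.
#' @export
as_gene_model_set <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "gene_id", "region_class")
                %in% names(df)))
  if (!"strand" %in% names(df)) df$strand <- "+"
  bad_class <- setdiff(unique(df$region_class), REGION_CLASSES)
  if (length(bad_class))
    stop("unknown region_class value(s): ", paste(bad_class, collapse = ", "))
  if (any(df$start > df$end))
    stop("empty or inverted interval(s) (start > end after conversion)")
  df$chrom <- normalize_chrom(df$chrom)
  class(df) <- c("gene_model_set", "data.frame")
  df
}

#' Write gene models back to BED-like form (inverse of read_gene_models)
#' @param models a \code{gene_model_set}.
#' @param path output path.
#' @export
write_gene_models <- function(models, path) {
  out <- data.frame(models$chrom, models$start - 1, models$end,
                    models$gene_id, ".", models$strand, models$region_class)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' All gene-model intervals covering a point
#'
#' @param models a \code{gene_model_set}.
#' @param chrom chromosome name.
#' @param pos 1-based position.
#' @return the covering rows of the model set (possibly none).
#' @export
gene_models_at <- function(models, chrom, pos) {
  m <- models[models$chrom == normalize_chrom(chrom), , drop = FALSE]
  m[m$start <= pos & m$end >= pos, , drop = FALSE]
}

#' Read a signature matrix from TSV
#'
#' First column holds the 96 context labels ("A[C>A]A", ...), remaining
#' columns one signature each (header row = signature IDs). Rows may be in
#' any order; they are canonicalized to the fixed 96-label order. Every
#' column must sum to 1 within 1e-3 (then renormalized exactly); entries
#' must be non-negative.
#'
#' @param path TSV file.
#' @return a \code{signature_matrix}: list with \code{contexts},
#'   \code{signature_ids} and the 96 x S matrix \code{W}.
#' @export
read_signature_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  labels <- df[[1]]
  W <- as.matrix(df[, -1, drop = FALSE])
  rownames(W) <- labels
  as_signature_matrix(W)
}

#' Construct/validate a signature matrix from a labelled numeric matrix
#'
#' @param W numeric matrix with the 96 canonical context labels as rownames
#'   and signature IDs as colnames.
#' @return a \code{signature_matrix} with rows in canonical order and
#'   columns renormalized to sum exactly to 1.
#' @export
as_signature_matrix <- function(W) {
  canon <- context_labels_96()
  if (is.null(rownames(W)) || nrow(W) != 96)
    stop("signature matrix must have 96 labelled context rows")
  missing_ctx <- setdiff(canon, rownames(W))
  if (length(missing_ctx))
    stop("missing context row(s): ", paste(utils::head(missing_ctx, 3),
                                           collapse = ", "))
  if (anyDuplicated(rownames(W))) stop("duplicated context rows")
  if (anyDuplicated(colnames(W))) stop("duplicated signature ids")
  if (any(W < 0)) stop("negative entries in signature matrix")
  W <- W[canon, , drop = FALSE]
  sums <- colSums(W)
  off <- which(abs(sums - 1) > 1e-3)
  if (length(off))
    stop("signature column(s) do not sum to 1 within 1e-3: ",
         paste(colnames(W)[off], collapse = ", "))
  W <- sweep(W, 2, sums, "/")
  structure(list(contexts = canon, signature_ids = colnames(W), W = W),
            class = "signature_matrix")
}

#' Write a signature matrix as TSV (inverse of read_signature_matrix)
#' @param sig a \code{signature_matrix}.
#' @param path output path.
#' @export
write_signature_matrix <- function(sig, path) {
  df <- data.frame(context = sig$contexts, sig$W, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read copy-number segments
#'
#' TSV with header columns sample_id (optional; single-sample files may omit
#' it), chrom, start, end, tcn and optionally minor_cn. Coordinates are
#' 1-based inclusive. Segments are sorted and must not overlap within a
#' sample.
#'
#' @param path TSV file.
#' @return a \code{cn_segments} data.frame.
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  as_cn_segments(df)
}

#' Validate a copy-number segment table
#' @param df data.frame with chrom, start, end, tcn, optionally sample_id
#'   and minor_cn.
#' @return sorted, validated \code{cn_segments}.
#' @export
as_cn_segments <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "tcn") %in% names(df)))
  if (!"sample_id" %in% names(df)) df$sample_id <- "sample"
  if (!"minor_cn" %in% names(df)) df$minor_cn <- NA_real_
  df$chrom <- normalize_chrom(df$chrom)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  df$tcn <- as.numeric(df$tcn)
  df$minor_cn <- as.numeric(df$minor_cn)
  if (any(df$start > df$end)) stop("segment with start > end")
  if (any(df$tcn < 0)) stop("negative total copy number")
  df <- df[order(df$sample_id, df$chrom, df$start), ]
  rownames(df) <- NULL
  for (key in unique(paste(df$sample_id, df$chrom))) {
    s <- df[paste(df$sample_id, df$chrom) == key, ]
    if (nrow(s) > 1) {
      ov <- which(s$start[-1] <= s$end[-nrow(s)])
      if (length(ov))
        stop("overlapping segments in sample ", s$sample_id[1],
             " chrom ", s$chrom[1], ": ",
             s$start[ov[1]], "-", s$end[ov[1]], " and ",
             s$start[ov[1] + 1], "-", s$end[ov[1] + 1])
    }
  }
  df <- df[, c("sample_id", "chrom", "start", "end", "tcn", "minor_cn")]
  class(df) <- c("cn_segments", "data.frame")
  df
}

#' Write copy-number segments as TSV
#' @param segments a \code{cn_segments}.
#' @param path output path.
#' @export
write_segments <- function(segments, path) {
  write.table(as.data.frame(segments), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a chromosome-arm definition table
#'
#' TSV with header columns chrom, arm ("p"/"q"), start, end; 1-based
#' inclusive; within a chromosome the p arm must precede and not overlap
#' the q arm.
#'
#' @param path TSV file.
#' @return an \code{arm_map}.
#' @export
read_arms <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  df$chrom <- normalize_chrom(df$chrom)
  validate_arm_map(df)
}
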