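#' @importFrom utils read.table write.table
NULL

VARIANT_COLUMNS <- c("chrom", "pos", "ref", "alt", "sample_id",
                     "ref_count", "alt_count", "caller_somatic")

#' Validate a variant table
#'
#' Enforces the record invariants: 1-based positive positions, non-negative
#' read counts, ref != alt, single-base ref and alt for SNVs (longer allele
#' strings are treated as indels). Depth is ref_count + alt_count; records
#' with missing counts are rejected rather than zero-filled because the
#' allele-fraction rules downstream divide by depth.
#'
#' @param df data.frame with columns chrom, pos, ref, alt, sample_id,
#'   ref_count, alt_count, caller_somatic and optionally context.
#' @return the validated table (class \code{variant_table}) with an added
#'   \code{depth} column and normalized chromosome names.
#' @export
validate_variant_table <- function(df) {
  missing_cols <- setdiff(VARIANT_COLUMNS, names(df))
  if (length(missing_cols))
    stop("variant table missing columns: ", paste(missing_cols, collapse = ", "))
  df$chrom <- normalize_chrom(df$chrom)
  df$pos <- as.numeric(df$pos)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  df$ref_count <- suppressWarnings(as.integer(df$ref_count))
  df$alt_count <- suppressWarnings(as.integer(df$alt_count))
  df$caller_somatic <- as.logical(as.integer(df$caller_somatic))
  if (!"context" %in% names(df)) df$context <- NA_character_

  bad <- which(
    is.na(df$pos) | df$pos < 1 |
      is.na(df$ref_count) | df$ref_count < 0 |
      is.na(df$alt_count) | df$alt_count < 0 |
      is.na(df$caller_somatic) |
      df$ref == df$alt | nchar(df$ref) == 0 | nchar(df$alt) == 0
  )
  if (length(bad))
    stop("invalid variant records at row(s): ", paste(bad, collapse = ", "))
  df$depth <- df$ref_count + df$alt_count
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Mutant allele fraction of each record
#'
#' MAF = alt_count / depth; zero-depth records get MAF 0.
#'
#' @param df a \code{variant_table}.
#' @return numeric vector.
#' @export
variant_maf <- function(df) {
  ifelse(df$depth > 0, df$alt_count / df$depth, 0)
}

#' Is a record an SNV?
#' @param df a \code{variant_table}.
#' @return logical vector; TRUE iff both alleles are single bases.
#' @export
is_snv <- function(df) nchar(df$ref) == 1L & nchar(df$alt) == 1L

#' Read a variant table from disk
#'
#' Two dialects are supported. \code{"tsv"}: a tab- or space-separated file
#' with a header naming the eight record columns (chrom, pos, ref, alt,
#' sample_id, ref_count, alt_count, caller_somatic) and an optional ninth
#' \code{context} column. \code{"vcf_subset"}: a VCFv4.2 file whose samples
#' carry AD-style allele depths; multi-allelic rows are split into one
#' record per alternate allele, and a record is flagged caller-somatic when
#' the INFO field contains the \code{SOMATIC} flag.
#'
#' @param path file path.
#' @param dialect \code{"tsv"} or \code{"vcf_subset"}.
#' @return a validated \code{variant_table} in input order.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf_subset")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv") {
    df <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                     colClasses = "character")
    if (!all(VARIANT_COLUMNS %in% names(df)))
      stop("malformed header in ", path, ": expected columns ",
           paste(VARIANT_COLUMNS, collapse = ", "))
    return(validate_variant_table(df))
  }
  read_vcf_subset(path)
}

read_vcf_subset <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0)
    return(validate_variant_table(empty_variant_table()))
  info <- vcfR::getINFO(v)
  somatic <- grepl("(^|;)SOMATIC(;|$|=)", info)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad)) stop("malformed VCF: no AD field in ", path)
  samples <- colnames(ad)
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (s in samples) {
      depths <- suppressWarnings(
        as.integer(strsplit(ad[i, s], ",", fixed = TRUE)[[1]]))
      if (length(depths) < 1 + length(alts) || anyNA(depths))
        stop("malformed AD entry at VCF row ", i, " sample ", s)
      for (j in seq_along(alts)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = fix$CHROM[i], pos = fix$POS[i], ref = fix$REF[i],
          alt = alts[j], sample_id = s, ref_count = depths[1],
          alt_count = depths[1 + j],
          caller_somatic = as.integer(somatic[i]),
          stringsAsFactors = FALSE)
      }
    }
  }
  validate_variant_table(do.call(rbind, rows))
}

empty_variant_table <- function() {
  data.frame(chrom = character(), pos = numeric(), ref = character(),
             alt = character(), sample_id = character(),
             ref_count = integer(), alt_count = integer(),
             caller_somatic = logical(), context = character(),
             stringsAsFactors = FALSE)
}

#' Write a variant table as TSV
#'
#' Writes the eight record columns plus context; reading the file back with
#' \code{read_variant_table(..., "tsv")} reproduces the records exactly.
#'
#' @param df a \code{variant_table}.
#' @param path output path.
#' @export
write_variant_table <- function(df, path) {
  out <- as.data.frame(df)[, c(VARIANT_COLUMNS, "context")]
  out$caller_somatic <- as.integer(out$caller_somatic)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
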