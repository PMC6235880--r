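REGION_PRIORITY <- c("splice_site", "CDS", "UTR3", "UTR5", "ncRNA_exon",
                     "intron", "intergenic")

EXONIC_CLASSES <- c("CDS", "UTR5", "UTR3", "ncRNA_exon")

# exon-class intervals imply 2 bp splice regions on their intronic flanks
splice_windows <- function(models) {
  ex <- models[models$region_class %in% EXONIC_CLASSES, , drop = FALSE]
  if (nrow(ex) == 0) return(empty_gene_models())
  rbind(
    data.frame(chrom = ex$chrom, start = pmax(1, ex$start - 2),
               end = ex$start - 1, gene_id = ex$gene_id,
               strand = ex$strand, region_class = "splice_site",
               stringsAsFactors = FALSE),
    data.frame(chrom = ex$chrom, start = ex$end + 1, end = ex$end + 2,
               gene_id = ex$gene_id, strand = ex$strand,
               region_class = "splice_site", stringsAsFactors = FALSE)
  )
}

#' Classify the genomic region of one variant
#'
#' Interval-based classification against a gene model set. When several
#' region classes cover the position the highest-priority one wins:
#' splice_site > CDS > UTR3 > UTR5 > ncRNA_exon > intron > intergenic.
#' A position within 2 bp of an exon/intron boundary (the 2 bp of intron
#' flanking any exonic interval) is a splice_site. Positions covered by no
#' interval are intergenic.
#'
#' @param chrom,pos variant coordinate (1-based).
#' @param models a \code{gene_model_set}.
#' @param ref,alt optional alleles; indels (allele lengths differing) are
#'   classified by their reference span rather than a single point.
#' @return list with \code{region_class} and \code{gene_ids} (character
#'   vector, empty for intergenic).
#' @export
classify_region <- function(chrom, pos, models, ref = "N", alt = "A") {
  end <- pos + max(nchar(ref) - 1, 0)
  hits <- rbind(
    as.data.frame(models),
    splice_windows(models)
  )
  hits <- hits[hits$chrom == normalize_chrom(chrom) &
                 hits$start <= end & hits$end >= pos, , drop = FALSE]
  if (nrow(hits) == 0)
    return(list(region_class = "intergenic", gene_ids = character()))
  cls <- REGION_PRIORITY[min(match(hits$region_class, REGION_PRIORITY))]
  list(region_class = cls,
       gene_ids = sort(unique(hits$gene_id[hits$region_class == cls])))
}

#' Frame classification of an indel
#'
#' @param ref,alt allele strings of unequal length.
#' @return \code{"frameshift"} if the length difference is not a multiple
#'   of 3, else \code{"inframe"}.
#' @export
classify_indel_frame <- function(ref, alt) {
  if (any(nchar(ref) == nchar(alt)))
    stop("not an indel: ref and alt have equal length")
  ifelse(abs(nchar(ref) - nchar(alt)) %% 3 != 0, "frameshift", "inframe")
}

#' Annotate a variant table against gene models
#'
#' Adds region_class, gene_ids (comma-joined), indel_frame and the
#' non_silent and mutation_of_interest flags to every record. Without
#' codon-level information every CDS SNV is treated as potentially
#' non-silent; if the input carries a logical \code{synonymous} column
#' (from a codon-aware annotator), synonymous CDS SNVs are excluded.
#'
#' @param variants data.frame with chrom, pos, ref, alt (a
#'   \code{variant_table} or the calls of a trio).
#' @param models a \code{gene_model_set}.
#' @return the input with annotation columns appended.
#' @export
annotate_variants <- function(variants, models) {
  all_iv <- rbind(as.data.frame(models), splice_windows(models))
  n <- nrow(variants)
  region <- rep("intergenic", n)
  genes <- character(n)
  vend <- variants$pos + pmax(nchar(variants$ref) - 1, 0)
  for (ch in unique(variants$chrom)) {
    vi <- which(variants$chrom == ch)
    iv <- all_iv[all_iv$chrom == ch, , drop = FALSE]
    if (nrow(iv) == 0) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(variants$pos[vi], vend[vi]),
      IRanges::IRanges(iv$start, iv$end))
    if (length(ov) == 0) next
    q <- S4Vectors::queryHits(ov)
    s <- S4Vectors::subjectHits(ov)
    for (u in unique(q)) {
      rows <- s[q == u]
      pr <- min(match(iv$region_class[rows], REGION_PRIORITY))
      cls <- REGION_PRIORITY[pr]
      region[vi[u]] <- cls
      genes[vi[u]] <- paste(
        sort(unique(iv$gene_id[rows][iv$region_class[rows] == cls])),
        collapse = ",")
    }
  }
  indel <- nchar(variants$ref) != nchar(variants$alt)
  variants$region_class <- region
  variants$gene_ids <- genes
  variants$indel_frame <- "not_applicable"
  if (any(indel))
    variants$indel_frame[indel] <-
      classify_indel_frame(variants$ref[indel], variants$alt[indel])
  syn <- if ("synonymous" %in% names(variants))
    variants$synonymous %in% TRUE else rep(FALSE, n)
  variants$non_silent <- region %in% c("CDS", "splice_site") & !syn
  variants$mutation_of_interest <- is_mutation_of_interest(variants)
  variants
}

#' Mutation-of-interest flag
#'
#' TRUE for variants causing potential protein-coding changes (non-silent
#' CDS or splice-site) and for exonic mutations on non-coding genes
#' (ncRNA_exon); indels additionally qualify when their span overlaps CDS.
#' 3'-UTR mutations are deliberately excluded — they form a separate
#' analysis channel.
#'
#' @param annotated data.frame with region_class, non_silent and allele
#'   columns (as produced by \code{\link{annotate_variants}}).
#' @return logical vector.
#' @export
is_mutation_of_interest <- function(annotated) {
  stopifnot(all(c("region_class", "non_silent") %in% names(annotated)))
  indel <- nchar(annotated$ref) != nchar(annotated$alt)
  (annotated$region_class %in% c("CDS", "splice_site") &
     annotated$non_silent) |
    annotated$region_class == "ncRNA_exon" |
    (indel & annotated$region_class == "CDS")
}
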