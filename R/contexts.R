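#' Canonical 96 trinucleotide substitution context labels
#'
#' Labels follow the pyrimidine-centered convention used for mutational
#' catalogs: six substitution classes (C>A, C>G, C>T, T>A, T>C, T>G), each
#' with the 16 combinations of 5' and 3' flanking bases, written as e.g.
#' \code{"A[C>A]A"}. Order is substitution-major, then 5' base, then 3' base,
#' each in alphabetical order.
#'
#' @return Character vector of length 96.
#' @export
context_labels_96 <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(f, t3) {
      paste0(f, "[", s, "]", t3)
    })))
  }), use.names = FALSE)
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(strsplit(toupper(x), ""), function(b) {
    paste(rev(unname(.COMP[b])), collapse = "")
  }, character(1))
}

#' Collapse an SNV to its pyrimidine-centered context label
#'
#' SNVs with a purine reference base (A or G) are reverse-complemented so
#' that every substitution is expressed with a C or T reference, the
#' convention under which 96-context catalogs are counted.
#'
#' @param ref,alt single reference/alternate bases.
#' @param context trinucleotide string (5' base, ref, 3' base).
#' @return The canonical label, e.g. \code{"A[C>A]A"}, or \code{NA} if the
#'   context contains an N or is inconsistent with \code{ref}.
#' @export
context_label <- function(ref, alt, context) {
  stopifnot(length(ref) == length(alt), length(ref) == length(context))
  context <- toupper(context)
  ref <- toupper(ref)
  alt <- toupper(alt)
  out <- rep(NA_character_, length(ref))
  ok <- !grepl("N", context) & nchar(context) == 3L &
    substr(context, 2, 2) == ref & ref != alt &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  purine <- ok & ref %in% c("A", "G")
  ctx <- context
  r <- ref
  a <- alt
  if (any(purine)) {
    ctx[purine] <- revcomp(context[purine])
    r[purine] <- unname(.COMP[ref[purine]])
    a[purine] <- unname(.COMP[alt[purine]])
  }
  out[ok] <- paste0(substr(ctx[ok], 1, 1), "[", r[ok], ">", a[ok], "]",
                    substr(ctx[ok], 3, 3))
  out
}

#' Decode a context label into its parts
#'
#' @param label character vector of labels like \code{"A[C>A]A"}.
#' @return data.frame with columns \code{five}, \code{ref}, \code{alt},
#'   \code{three} and the reconstructed \code{context} trinucleotide.
#' @export
parse_context_label <- function(label) {
  stopifnot(grepl("^[ACGT]\\[[CT]>[ACGT]\\][ACGT]$", label))
  data.frame(
    five = substr(label, 1, 1),
    ref = substr(label, 3, 3),
    alt = substr(label, 5, 5),
    three = substr(label, 7, 7),
    context = paste0(substr(label, 1, 1), substr(label, 3, 3),
                     substr(label, 7, 7)),
    stringsAsFactors = FALSE
  )
}
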