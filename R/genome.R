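#' Default genome model: the 22 human autosomes
#'
#' Chromosome lengths of the hs37d5 assembly (GRCh37 primary autosomes),
#' used as the default coordinate space for synthetic cohorts. Chromosome
#' names carry no "chr" prefix, matching the assembly's naming.
#'
#' @return data.frame with columns \code{chrom} (character) and
#'   \code{length} (numeric, bp).
#' @export
default_genome_model <- function() {
  data.frame(
    chrom = as.character(1:22),
    length = c(
      249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
      159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
      115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
      59128983, 63025520, 48129895, 51304566
    ),
    stringsAsFactors = FALSE
  )
}

#' Default chromosome-arm map
#'
#' A simple arm map over a genome model: each chromosome is split at its
#' midpoint into a p arm (first half) and q arm (second half). Real analyses
#' should supply a cytoband-derived arm file via \code{\link{read_arms}};
#' this default exists so synthetic cohorts have a complete arm definition.
#'
#' @param genome data.frame as from \code{\link{default_genome_model}}.
#' @return arm map data.frame with columns \code{chrom}, \code{arm}
#'   ("p"/"q"), \code{start}, \code{end} (1-based inclusive).
#' @export
default_arm_map <- function(genome = default_genome_model()) {
  mid <- floor(genome$length / 2)
  out <- rbind(
    data.frame(chrom = genome$chrom, arm = "p", start = 1, end = mid,
               stringsAsFactors = FALSE),
    data.frame(chrom = genome$chrom, arm = "q", start = mid + 1,
               end = genome$length, stringsAsFactors = FALSE)
  )
  out <- out[order(match(out$chrom, genome$chrom), out$start), ]
  rownames(out) <- NULL
  validate_arm_map(out)
}

validate_arm_map <- function(arms) {
  stopifnot(all(c("chrom", "arm", "start", "end") %in% names(arms)))
  stopifnot(all(arms$arm %in% c("p", "q")), all(arms$start <= arms$end))
  for (ch in unique(arms$chrom)) {
    a <- arms[arms$chrom == ch, ]
    if (nrow(a) == 2) {
      p <- a[a$arm == "p", ]
      q <- a[a$arm == "q", ]
      if (nrow(p) == 1 && nrow(q) == 1 && p$end >= q$start)
        stop("arms overlap or p does not precede q on chromosome ", ch)
    }
  }
  class(arms) <- c("arm_map", "data.frame")
  arms
}

# strip any chr prefix; hs37d5 naming
normalize_chrom <- function(chrom) sub("^chr", "", as.character(chrom))
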