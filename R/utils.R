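# Internal helpers shared across modules.

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# integer-valued check that tolerates doubles holding whole numbers
is_whole <- function(x) {
  is.numeric(x) & !is.na(x) & abs(x - round(x)) < 1e-8
}

# format genomic coordinates without scientific notation
fmt_coord <- function(x) {
  format(x, scientific = FALSE, trim = TRUE)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

# half-open intervals [s1,e1) and [s2,e2) share >= 1 bp
ivl_overlap <- function(s1, e1, s2, e2) {
  pmax(s1, s2) < pmin(e1, e2)
}

#' Jaccard index of two genomic intervals
#'
#' Length of the intersection divided by length of the union of two
#' half-open intervals. Intervals on different chromosomes have Jaccard 0.
#'
#' @param chrom1,start1,end1 first interval (0-based half-open).
#' @param chrom2,start2,end2 second interval.
#' @return A number in \[0, 1\].
#' @examples
#' interval_jaccard("chr1", 0, 2e6, "chr1", 1e6, 3e6)  # 1/3
#' @export
interval_jaccard <- function(chrom1, start1, end1, chrom2, start2, end2) {
  if (chrom1 != chrom2) return(0)
  inter <- max(0, min(end1, end2) - max(start1, start2))
  if (inter == 0) return(0)
  union <- (end1 - start1) + (end2 - start2) - inter
  inter / union
}

# GRanges from 0-based half-open columns; empty input allowed.
# `universe` fixes the seqlevels so ranges from different sets compare
# without seqlevel mismatches.
as_gr <- function(chrom, start, end, universe = NULL) {
  chrom <- as.character(chrom)
  if (is.null(universe)) universe <- unique(chrom)
  GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = universe),
    ranges = IRanges::IRanges(start = start + 1, end = end)
  )
}
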