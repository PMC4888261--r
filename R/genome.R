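#' Genome layout: named chromosomes with lengths
#'
#' The coordinate frame for every scan. Chromosome order is preserved
#' exactly as given; it defines the order of all downstream output.
#' Unplaced sequences (e.g. a `chrUn` entry) are ordinary chromosomes here,
#' so sites that cannot be assigned to a placed chromosome remain scannable.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths in bp (> 0).
#' @return A `genome_layout`: a data frame with columns `chrom` and
#'   `length`, one row per chromosome, in input order.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(5e6, 3e6))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  if (length(chrom) == 0L) stopf("genome must contain at least one chromosome")
  if (length(chrom) != base::length(length)) {
    stopf("chrom and length must have equal length")
  }
  if (anyDuplicated(chrom)) {
    stopf("duplicate chromosome name(s): %s",
          paste(unique(chrom[duplicated(chrom)]), collapse = ", "))
  }
  if (!all(is_whole(length)) || any(length <= 0)) {
    stopf("chromosome lengths must be positive integers")
  }
  out <- data.frame(chrom = chrom, length = as.numeric(length),
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' Read a chromosome-sizes file
#'
#' Parses a UCSC-style chrom.sizes file: one chromosome per line, name and
#' integer length separated by whitespace. Lines starting with `#` and
#' blank lines are ignored. Extra columns beyond the first two are ignored.
#'
#' @param path path to the chrom.sizes file.
#' @return A [genome_layout()] in file order.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stopf("genome file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0L) stopf("genome file is empty: %s", path)
  nm <- character(length(keep))
  ln <- numeric(length(keep))
  for (i in seq_along(keep)) {
    fields <- strsplit(trimws(lines[keep[i]]), "[ \t]+")[[1]]
    if (length(fields) < 2L) {
      stopf("malformed chrom.sizes line %d: %s", keep[i], lines[keep[i]])
    }
    len <- suppressWarnings(as.numeric(fields[2]))
    if (is.na(len) || !is_whole(len)) {
      stopf("malformed chrom.sizes line %d: length '%s' is not an integer",
            keep[i], fields[2])
    }
    nm[i] <- fields[1]
    ln[i] <- len
  }
  if (any(ln <= 0)) {
    bad <- keep[which(ln <= 0)[1]]
    stopf("non-positive chromosome length at line %d", bad)
  }
  if (anyDuplicated(nm)) {
    stopf("duplicate chromosome name(s): %s",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  genome_layout(nm, ln)
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("<genome_layout> %d chromosome(s), %s bp total\n",
              nrow(x), fmt_coord(sum(x$length))))
  print.data.frame(utils::head(as.data.frame(x), 25), row.names = FALSE)
  if (nrow(x) > 25) cat(sprintf("... and %d more\n", nrow(x) - 25))
  invisible(x)
}

genome_total_length <- function(genome) sum(genome$length)

chrom_length <- function(genome, chrom) {
  genome$length[match(chrom, genome$chrom)]
}
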