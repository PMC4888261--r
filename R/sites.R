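#' Construct a site set
#'
#' A labeled collection of genomic sites (genes or DMRs). Each site is an
#' interval in 0-based half-open coordinates, reduced to a representative
#' point used for window counting. Sites on chromosomes absent from the
#' genome layout are dropped with a message (their count is retained in
#' the `n_dropped` attribute); this mirrors sites in unplaced or
#' uncharacterized regions that a layout may choose not to carry.
#'
#' @param chrom,start,end site intervals (0-based half-open).
#' @param site_id unique identifiers; `NULL` to synthesize `<label>_<n>`.
#' @param label dataset label (e.g. `"FT"`, `"DMR"`, `"BKG"`).
#' @param site_type `"gene"` or `"dmr"`.
#' @param genome a [genome_layout()].
#' @param point_rule `"midpoint"` (default) places the representative point
#'   at `floor((start+end)/2)`; `"start"` uses the interval start.
#' @return A `site_set`: data frame with columns `chrom`, `start`, `end`,
#'   `site_id`, `point`; attributes `label`, `site_type`, `genome`,
#'   `n_dropped`.
#' @export
site_set <- function(chrom, start, end, site_id = NULL, label,
                     site_type = c("gene", "dmr"), genome,
                     point_rule = c("midpoint", "start")) {
  site_type <- match.arg(site_type)
  point_rule <- match.arg(point_rule)
  stopifnot(inherits(genome, "genome_layout"))
  n <- length(start)
  chrom <- rep(as.character(chrom), length.out = n)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (is.null(site_id)) {
    site_id <- if (n) paste0(label, "_", seq_len(n)) else character(0)
  }
  site_id <- as.character(site_id)
  if (length(start) != n || length(end) != n || length(site_id) != n) {
    stopf("chrom, start, end, site_id must have equal length")
  }

  bad <- which(!(is_whole(start) & is_whole(end) & end > start & start >= 0))
  if (length(bad)) {
    stopf("invalid site interval at record %d (%s:%s-%s): need 0 <= start < end",
          bad[1], chrom[bad[1]], fmt_coord(start[bad[1]]), fmt_coord(end[bad[1]]))
  }

  known <- chrom %in% genome$chrom
  n_dropped <- sum(!known)
  if (n_dropped > 0) {
    message(sprintf("site_set '%s': dropped %d site(s) on chromosome(s) absent from genome (%s)",
                    label, n_dropped,
                    paste(unique(chrom[!known]), collapse = ", ")))
    chrom <- chrom[known]; start <- start[known]; end <- end[known]
    site_id <- site_id[known]
  }

  over <- which(end > chrom_length(genome, chrom))
  if (length(over)) {
    stopf("site %s extends past the end of %s (%s > %s)",
          site_id[over[1]], chrom[over[1]], fmt_coord(end[over[1]]),
          fmt_coord(chrom_length(genome, chrom[over[1]])))
  }
  if (anyDuplicated(site_id)) {
    stopf("duplicate site_id(s) in set '%s': %s", label,
          paste(utils::head(unique(site_id[duplicated(site_id)]), 3), collapse = ", "))
  }

  point <- switch(point_rule,
                  midpoint = floor((start + end) / 2),
                  start = start)

  out <- data.frame(chrom = chrom, start = start, end = end,
                    site_id = site_id, point = point,
                    stringsAsFactors = FALSE)
  structure(out,
            label = label, site_type = site_type, genome = genome,
            point_rule = point_rule, n_dropped = n_dropped,
            class = c("site_set", "data.frame"))
}

#' Read a BED site list
#'
#' Reads BED3/BED4 (tab- or space-separated, `#` comment lines ignored,
#' no header) into a [site_set()]. Coordinates are 0-based half-open per
#' the BED convention. A missing name column is synthesized as
#' `<label>_<n>` by record number.
#'
#' @inheritParams site_set
#' @param path path to the BED file.
#' @return A `site_set`.
#' @export
read_sites <- function(path, label, site_type = c("gene", "dmr"), genome,
                       point_rule = c("midpoint", "start")) {
  if (!file.exists(path)) stopf("site file not found: %s", path)
  df <- tryCatch(
    utils::read.table(path, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE,
                      colClasses = NA, fill = TRUE),
    error = function(e) stopf("failed to read BED file %s: %s", path,
                              conditionMessage(e)))
  if (ncol(df) < 3L) stopf("BED file %s has fewer than 3 columns", path)
  ids <- if (ncol(df) >= 4L) as.character(df[[4]]) else NULL
  if (!is.null(ids)) {
    # BED4 name column may be absent on some records
    blank <- is.na(ids) | ids == ""
    ids[blank] <- paste0(label, "_", which(blank))
  }
  site_set(chrom = df[[1]], start = df[[2]], end = df[[3]], site_id = ids,
           label = label, site_type = site_type, genome = genome,
           point_rule = point_rule)
}

#' Write a site set as BED4
#'
#' @param sites a [site_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  stopifnot(inherits(sites, "site_set"))
  df <- data.frame(sites$chrom, fmt_coord(sites$start), fmt_coord(sites$end),
                   sites$site_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.site_set <- function(x, ...) {
  cat(sprintf("<site_set> '%s' (%s): %d site(s) on %d chromosome(s)",
              attr(x, "label"), attr(x, "site_type"), nrow(x),
              length(unique(x$chrom))))
  if (attr(x, "n_dropped") > 0) {
    cat(sprintf(" [%d dropped at read]", attr(x, "n_dropped")))
  }
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  invisible(x)
}

site_label <- function(sites) attr(sites, "label")
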