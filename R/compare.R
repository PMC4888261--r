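#' Do two clusters overlap?
#'
#' Clusters (or any half-open intervals with a `chrom`) overlap when they
#' share the chromosome and at least 1 bp: `max(starts) < min(ends)`.
#' Abutting half-open intervals do not overlap.
#'
#' @param a,b lists or one-row data frames with `chrom`, `start`, `end`.
#' @return `TRUE` or `FALSE`.
#' @export
clusters_overlap <- function(a, b) {
  a$chrom == b$chrom && max(a$start, b$start) < min(a$end, b$end)
}

#' Remove target clusters that overlap a background cluster set
#'
#' A target cluster is removed whole (never trimmed) when it overlaps any
#' background cluster by at least 1 bp, or — when `min_frac > 0` — when
#' some background cluster achieves at least that reciprocal overlap
#' fraction (intersection length relative to both intervals).
#'
#' The operation is idempotent: the retained set, subtracted again against
#' the same background, is unchanged.
#'
#' @param target a [cluster_set()].
#' @param background a [cluster_set()] (e.g. clusters of all annotated
#'   genes, capturing the genome's inherent gene clumping).
#' @param min_frac minimum reciprocal overlap fraction required for
#'   removal; 0 (default) removes on any >= 1 bp overlap.
#' @return A `subtraction_result`: list with `retained` and `removed`
#'   cluster sets and counts `n_input`, `n_removed`, `n_retained`.
#' @export
subtract_background <- function(target, background, min_frac = 0) {
  stopifnot(inherits(target, "cluster_set"), inherits(background, "cluster_set"),
            min_frac >= 0, min_frac <= 1)
  n <- nrow(target)
  if (n == 0L || nrow(background) == 0L) {
    removed_idx <- logical(n)
  } else {
    uni <- unique(c(target$chrom, background$chrom))
    tg <- as_gr(target$chrom, target$start, target$end, universe = uni)
    bg <- as_gr(background$chrom, background$start, background$end,
                universe = uni)
    hits <- GenomicRanges::findOverlaps(tg, bg)
    if (min_frac > 0 && length(hits)) {
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      inter <- pmin(target$end[qi], background$end[si]) -
        pmax(target$start[qi], background$start[si])
      ok <- inter / (target$end[qi] - target$start[qi]) >= min_frac &
        inter / (background$end[si] - background$start[si]) >= min_frac
      qi <- qi[ok]
      removed_idx <- seq_len(n) %in% qi
    } else {
      removed_idx <- seq_len(n) %in% S4Vectors::queryHits(hits)
    }
  }
  subset_cs <- function(cs, keep) {
    cluster_set(as.data.frame(cs)[keep, , drop = FALSE],
                member_site_ids = attr(cs, "member_site_ids")[keep],
                label = attr(cs, "label"),
                source_site_label = attr(cs, "source_site_label"),
                params = attr(cs, "params"), genome = attr(cs, "genome"))
  }
  out <- list(retained = subset_cs(target, !removed_idx),
              removed = subset_cs(target, removed_idx),
              n_input = n, n_removed = sum(removed_idx),
              n_retained = sum(!removed_idx))
  class(out) <- "subtraction_result"
  out
}

#' @export
print.subtraction_result <- function(x, ...) {
  cat(sprintf("<subtraction_result> %d input cluster(s): %d removed (overlap background), %d retained\n",
              x$n_input, x$n_removed, x$n_retained))
  invisible(x)
}

#' Pairwise overlap matrix of cluster sets
#'
#' Entry (i, j), i != j, is the number of overlapping cluster pairs
#' between set i and set j (each pair counted once, so the matrix is
#' symmetric); the diagonal holds each set's cluster count.
#'
#' @param sets list of [cluster_set()]s.
#' @param labels column/row labels; defaults to each set's label.
#' @return A symmetric integer matrix with the labels as dimnames.
#' @export
overlap_matrix <- function(sets, labels = NULL) {
  stopifnot(length(sets) >= 1, all(vapply(sets, inherits, TRUE, "cluster_set")))
  if (is.null(labels)) {
    labels <- vapply(sets, function(s) attr(s, "label"), character(1))
  }
  if (anyDuplicated(labels)) stopf("cluster-set labels must be unique")
  n <- length(sets)
  uni <- unique(unlist(lapply(sets, function(s) s$chrom)))
  grs <- lapply(sets, function(s) as_gr(s$chrom, s$start, s$end,
                                        universe = uni))
  m <- matrix(0L, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    m[i, i] <- nrow(sets[[i]])
    if (i < n) {
      for (j in seq((i + 1), n)) {
        cnt <- length(GenomicRanges::findOverlaps(grs[[i]], grs[[j]]))
        m[i, j] <- m[j, i] <- cnt
      }
    }
  }
  m
}

#' Write an overlap matrix as TSV with a label header row and column
#'
#' @param m matrix from [overlap_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_overlap_matrix <- function(m, path) {
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fraction of sites falling inside a cluster set
#'
#' Counts the site points lying inside any cluster span and returns the
#' count plus the unrounded percentage. Summary tables round the
#' percentage to the nearest integer (half away from zero).
#'
#' @param sites a nonempty [site_set()].
#' @param clusters a [cluster_set()].
#' @return List with `n_in` and `percent`.
#' @examples
#' # 221 of 1052 sites inside clusters -> 21.0 percent
#' @export
percent_in_clusters <- function(sites, clusters) {
  stopifnot(inherits(sites, "site_set"), inherits(clusters, "cluster_set"))
  if (nrow(sites) == 0L) {
    stopf("percentage undefined for an empty site set")
  }
  if (nrow(clusters) == 0L) {
    return(list(n_in = 0L, percent = 0))
  }
  uni <- unique(c(sites$chrom, clusters$chrom))
  pts <- as_gr(sites$chrom, sites$point, sites$point + 1, universe = uni)
  cl <- as_gr(clusters$chrom, clusters$start, clusters$end, universe = uni)
  n_in <- sum(GenomicRanges::countOverlaps(pts, cl) > 0)
  list(n_in = as.integer(n_in), percent = 100 * n_in / nrow(sites))
}
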