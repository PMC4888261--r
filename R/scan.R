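#' Scan parameters
#'
#' Parameters of the sliding-window over-representation scan. Defaults are
#' the standard configuration for mammalian-genome scans of ~10^3 sites:
#' a 2 Mb window shifted 50 kb at a time, raw one-sided p < 0.05 for
#' window significance, and merging of significant windows that overlap or
#' lie within 50 kb of each other.
#'
#' @param window_size window width in bp.
#' @param step shift between consecutive window starts in bp
#'   (`0 < step <= window_size`).
#' @param alpha significance level for a window's one-sided p-value.
#' @param merge_gap maximum gap in bp between significant windows that are
#'   merged into one cluster.
#' @param null_scope `"genome"` pools window counts genome-wide to form the
#'   null mean/sd; `"per_chromosome"` computes them per chromosome.
#' @param sd_mode `"sample"` (n-1 denominator) or `"population"`.
#' @param mt_correction `"none"` (raw p-values, the classical setting) or
#'   `"bh"` (Benjamini-Hochberg adjustment across all windows before
#'   thresholding).
#' @return A `scan_params` list.
#' @export
scan_params <- function(window_size = 2e6, step = 5e4, alpha = 0.05,
                        merge_gap = 5e4,
                        null_scope = c("genome", "per_chromosome"),
                        sd_mode = c("sample", "population"),
                        mt_correction = c("none", "bh")) {
  null_scope <- match.arg(null_scope)
  sd_mode <- match.arg(sd_mode)
  mt_correction <- match.arg(mt_correction)
  if (!is_whole(window_size) || window_size <= 0) {
    stopf("window_size must be a positive integer")
  }
  if (!is_whole(step) || step <= 0 || step > window_size) {
    stopf("step must satisfy 0 < step <= window_size")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stopf("alpha must lie in (0, 1)")
  }
  if (!is_whole(merge_gap) || merge_gap < 0) {
    stopf("merge_gap must be a non-negative integer")
  }
  structure(list(window_size = window_size, step = step, alpha = alpha,
                 merge_gap = merge_gap, null_scope = null_scope,
                 sd_mode = sd_mode, mt_correction = mt_correction),
            class = "scan_params")
}

#' @export
print.scan_params <- function(x, ...) {
  cat(sprintf(
    "<scan_params> window %s bp, step %s bp, alpha %g, merge_gap %s bp,\n  null_scope=%s, sd_mode=%s, mt_correction=%s\n",
    fmt_coord(x$window_size), fmt_coord(x$step), x$alpha,
    fmt_coord(x$merge_gap), x$null_scope, x$sd_mode, x$mt_correction))
  invisible(x)
}

#' Tile a genome with sliding windows
#'
#' Each chromosome is tiled separately, from its start to its end. A
#' chromosome shorter than the window yields one window spanning it
#' entirely. Otherwise window starts are `0, step, 2*step, ...` for every
#' start `<= L - window_size`, plus a final right-anchored window
#' `[L - window_size, L)` when `L - window_size` is not already a start,
#' so that every window is full length and the chromosome end is covered.
#'
#' @param genome a [genome_layout()].
#' @param params a [scan_params()].
#' @return Data frame with columns `chrom`, `start`, `end` in genome order.
#' @export
make_windows <- function(genome, params = scan_params()) {
  stopifnot(inherits(genome, "genome_layout"), inherits(params, "scan_params"))
  w <- params$window_size
  step <- params$step
  pieces <- lapply(seq_len(nrow(genome)), function(i) {
    L <- genome$length[i]
    if (L <= w) {
      starts <- 0
      ends <- L
    } else {
      starts <- seq(0, L - w, by = step)
      if (starts[length(starts)] != L - w) starts <- c(starts, L - w)
      ends <- starts + w
    }
    data.frame(chrom = genome$chrom[i], start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

#' Count site points per window
#'
#' Fills the `count` column: the number of representative site points `p`
#' with `start <= p < end`. A point inside several overlapping windows is
#' counted in each of them.
#'
#' @param windows window data frame from [make_windows()].
#' @param sites a [site_set()] on the same genome.
#' @return `windows` with a `count` column added.
#' @export
count_in_windows <- function(windows, sites) {
  stopifnot(inherits(sites, "site_set"))
  counts <- integer(nrow(windows))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    pts <- sort(sites$point[sites$chrom == ch])
    if (length(pts) == 0L) next
    # points in [s, e) = (# points < e) - (# points < s); points are integers
    counts[wi] <- findInterval(windows$end[wi] - 0.5, pts) -
      findInterval(windows$start[wi] - 0.5, pts)
  }
  windows$count <- counts
  windows
}

#' Score windows with a one-sided z-test for over-representation
#'
#' Within the null scope (genome-wide by default) the null mean `mu` and
#' standard deviation `sigma` are the mean and sd of the observed window
#' counts; each window's `z = (count - mu) / sigma` and
#' `p = P(Z > z)` under the standard normal. Only over-represented
#' (high-count) windows can be significant; depleted windows get p > 0.5.
#' If `sigma` is zero the null is degenerate: all z are `NA`, all p are 1,
#' and a warning is raised.
#'
#' @param windows window data frame with `count` filled.
#' @param params a [scan_params()].
#' @param genome a [genome_layout()] (defines chromosome order for the
#'   per-chromosome scope).
#' @return A list with `windows` (columns `z`, `p`, and `p_adj` when
#'   `mt_correction = "bh"`), `null_mean` and `null_sd` (named vectors,
#'   one entry per scope).
#' @export
score_windows <- function(windows, params = scan_params(), genome = NULL) {
  stopifnot(inherits(params, "scan_params"), !is.null(windows$count))
  scopes <- if (params$null_scope == "genome") {
    list(genome = seq_len(nrow(windows)))
  } else {
    split(seq_len(nrow(windows)), factor(windows$chrom,
                                         levels = unique(windows$chrom)))
  }
  windows$z <- NA_real_
  windows$p <- NA_real_
  null_mean <- null_sd <- stats::setNames(numeric(length(scopes)), names(scopes))
  for (k in seq_along(scopes)) {
    idx <- scopes[[k]]
    if (length(idx) < 2L) {
      stopf("insufficient data: scope '%s' has %d window(s); need >= 2",
            names(scopes)[k], length(idx))
    }
    counts <- windows$count[idx]
    mu <- mean(counts)
    sigma <- if (params$sd_mode == "sample") {
      stats::sd(counts)
    } else {
      sqrt(mean((counts - mu)^2))
    }
    null_mean[k] <- mu
    null_sd[k] <- sigma
    if (sigma == 0) {
      warnf("degenerate null in scope '%s': all window counts equal (%g); p set to 1",
            names(scopes)[k], mu)
      windows$p[idx] <- 1
    } else {
      z <- (counts - mu) / sigma
      windows$z[idx] <- z
      windows$p[idx] <- stats::pnorm(z, lower.tail = FALSE)
    }
  }
  if (params$mt_correction == "bh") {
    windows$p_adj <- stats::p.adjust(windows$p, method = "BH")
  }
  list(windows = windows, null_mean = null_mean, null_sd = null_sd)
}

# p-values actually compared to alpha (adjusted under BH)
effective_p <- function(windows, params) {
  if (params$mt_correction == "bh") windows$p_adj else windows$p
}

#' Merge significant windows into clusters
#'
#' Windows with p < alpha (after multiple-testing correction, if enabled)
#' on the same chromosome whose intervals overlap or are separated by at
#' most `merge_gap` bp are merged transitively. Each cluster spans the
#' union of its windows; its p-value is the minimum p among the merged
#' windows; its member sites are all site points inside the cluster span.
#'
#' @param scored result of [score_windows()].
#' @param sites the scanned [site_set()].
#' @param params a [scan_params()].
#' @param label cluster-set label; defaults to the site-set label.
#' @return A [cluster_set()].
#' @export
call_clusters <- function(scored, sites, params = scan_params(),
                          label = NULL) {
  windows <- scored$windows
  stopifnot(!is.null(windows$p), inherits(sites, "site_set"))
  if (is.null(label)) label <- site_label(sites)
  p_use <- effective_p(windows, params)
  sig <- which(p_use < params$alpha)

  rows <- list()
  members <- list()
  k <- 0L
  for (ch in unique(windows$chrom)) {
    si <- sig[windows$chrom[sig] == ch]
    if (length(si) == 0L) next
    si <- si[order(windows$start[si])]
    cs <- windows$start[si[1]]
    ce <- windows$end[si[1]]
    cp <- p_use[si[1]]
    nw <- 1L
    flush <- function(cs, ce, cp, nw) {
      k <<- k + 1L
      in_span <- sites$chrom == ch & sites$point >= cs & sites$point < ce
      members[[k]] <<- sites$site_id[in_span]
      rows[[k]] <<- data.frame(
        cluster_id = paste0(label, "_c", k), chrom = ch,
        start = cs, end = ce, n_sites = sum(in_span), p_value = cp,
        n_windows_merged = nw, stringsAsFactors = FALSE)
    }
    if (length(si) > 1L) {
      for (j in si[-1]) {
        if (windows$start[j] - ce <= params$merge_gap) {
          ce <- max(ce, windows$end[j])
          cp <- min(cp, p_use[j])
          nw <- nw + 1L
        } else {
          flush(cs, ce, cp, nw)
          cs <- windows$start[j]; ce <- windows$end[j]
          cp <- p_use[j]; nw <- 1L
        }
      }
    }
    flush(cs, ce, cp, nw)
  }

  cluster_set(
    clusters = if (k) do.call(rbind, rows) else NULL,
    member_site_ids = members,
    label = label, source_site_label = site_label(sites),
    params = params, genome = attr(sites, "genome"))
}

#' Construct a cluster set
#'
#' @param clusters data frame with columns `cluster_id`, `chrom`, `start`,
#'   `end`, `n_sites`, `p_value`, `n_windows_merged` (or `NULL` for an
#'   empty set).
#' @param member_site_ids list of character vectors, parallel to the rows.
#' @param label set label.
#' @param source_site_label label of the site set the clusters were called
#'   from.
#' @param params the [scan_params()] used (may be `NULL` for sets read
#'   from disk).
#' @param genome the [genome_layout()].
#' @return A `cluster_set` data frame with those attributes.
#' @export
cluster_set <- function(clusters = NULL, member_site_ids = list(),
                        label, source_site_label = label, params = NULL,
                        genome = NULL) {
  if (is.null(clusters) || nrow(clusters) == 0L) {
    clusters <- data.frame(cluster_id = character(0), chrom = character(0),
                           start = numeric(0), end = numeric(0),
                           n_sites = integer(0), p_value = numeric(0),
                           n_windows_merged = integer(0),
                           stringsAsFactors = FALSE)
    member_site_ids <- list()
  }
  if (!is.null(genome)) {
    ord <- order(match(clusters$chrom, genome$chrom), clusters$start)
    clusters <- clusters[ord, , drop = FALSE]
    member_site_ids <- member_site_ids[ord]
    rownames(clusters) <- NULL
  }
  structure(clusters,
            member_site_ids = member_site_ids, label = label,
            source_site_label = source_site_label, params = params,
            genome = genome,
            class = c("cluster_set", "data.frame"))
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> '%s': %d cluster(s), %d member site(s)\n",
              attr(x, "label"), nrow(x), sum(x$n_sites)))
  if (nrow(x)) {
    print.data.frame(utils::head(as.data.frame(x), 15), row.names = FALSE)
    if (nrow(x) > 15) cat(sprintf("... and %d more\n", nrow(x) - 15))
  }
  invisible(x)
}

#' Sliding-window cluster scan
#'
#' The full scan: tile the genome, count site points per window, z-score
#' the counts against the pooled null, and merge significant windows into
#' clusters. Deterministic for fixed inputs.
#'
#' @param sites a [site_set()].
#' @param genome a [genome_layout()]; defaults to the site set's genome.
#' @param params a [scan_params()].
#' @return A `cluster_scan` object: list with `label`, `params`,
#'   `windows` (count/z/p per window), `null_mean`, `null_sd`, `clusters`
#'   (a [cluster_set()]), `n_sites`.
#' @examples
#' g <- genome_layout("chr1", 10e6)
#' s <- site_set("chr1", seq(0, 9.9e6, by = 1e5), seq(0, 9.9e6, by = 1e5) + 1000,
#'               label = "demo", site_type = "gene", genome = g)
#' res <- cluster_scan(s, params = scan_params(window_size = 1e6, step = 5e5))
#' @export
cluster_scan <- function(sites, genome = attr(sites, "genome"),
                         params = scan_params()) {
  stopifnot(inherits(sites, "site_set"), inherits(genome, "genome_layout"),
            inherits(params, "scan_params"))
  windows <- make_windows(genome, params)
  windows <- count_in_windows(windows, sites)
  scored <- score_windows(windows, params, genome)
  clusters <- call_clusters(scored, sites, params)
  structure(list(label = site_label(sites), params = params,
                 genome = genome, windows = scored$windows,
                 null_mean = scored$null_mean, null_sd = scored$null_sd,
                 clusters = clusters, n_sites = nrow(sites)),
            class = "cluster_scan")
}

#' @export
print.cluster_scan <- function(x, ...) {
  cat(sprintf("<cluster_scan> '%s': %d sites, %d windows, %d cluster(s)\n",
              x$label, x$n_sites, nrow(x$windows), nrow(x$clusters)))
  cat(sprintf("  null mean %s, sd %s (%s scope)\n",
              paste(signif(x$null_mean, 4), collapse = ", "),
              paste(signif(x$null_sd, 4), collapse = ", "),
              x$params$null_scope))
  invisible(x)
}

#' @export
summary.cluster_scan <- function(object, ...) {
  cl <- object$clusters
  pct <- if (object$n_sites > 0) 100 * sum(cl$n_sites) / object$n_sites else NA
  out <- list(label = object$label, n_sites = object$n_sites,
              n_windows = nrow(object$windows),
              n_significant_windows =
                sum(effective_p(object$windows, object$params) <
                      object$params$alpha),
              n_clusters = nrow(cl),
              n_sites_in_clusters = sum(cl$n_sites),
              percent_in_clusters = pct,
              null_mean = object$null_mean, null_sd = object$null_sd,
              clusters = as.data.frame(cl))
  class(out) <- "summary.cluster_scan"
  out
}

#' @export
print.summary.cluster_scan <- function(x, ...) {
  cat(sprintf("Sliding-window scan of '%s'\n", x$label))
  cat(sprintf("  %d sites; %d windows (%d significant); null mean %s, sd %s\n",
              x$n_sites, x$n_windows, x$n_significant_windows,
              paste(signif(x$null_mean, 4), collapse = ", "),
              paste(signif(x$null_sd, 4), collapse = ", ")))
  cat(sprintf("  %d cluster(s) holding %d sites (%s%% of set)\n",
              x$n_clusters, x$n_sites_in_clusters,
              ifelse(is.na(x$percent_in_clusters), "NA",
                     round_half_up(x$percent_in_clusters))))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Plot window counts and called clusters along the genome
#'
#' One panel per chromosome: window counts at window midpoints, the null
#' mean (dashed) and the significance threshold `mu + z_alpha * sigma`
#' (dotted), with cluster spans shaded.
#'
#' @param x a `cluster_scan`.
#' @param chroms chromosomes to show (default: all with windows).
#' @param ... passed to [graphics::plot()].
#' @export
plot.cluster_scan <- function(x, chroms = NULL, ...) {
  w <- x$windows
  if (is.null(chroms)) chroms <- unique(w$chrom)
  old <- graphics::par(mfrow = c(length(chroms), 1),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  zcrit <- stats::qnorm(1 - x$params$alpha)
  for (ch in chroms) {
    wi <- w[w$chrom == ch, ]
    mid <- (wi$start + wi$end) / 2
    mu <- if (x$params$null_scope == "genome") x$null_mean[["genome"]] else x$null_mean[[ch]]
    sig <- if (x$params$null_scope == "genome") x$null_sd[["genome"]] else x$null_sd[[ch]]
    graphics::plot(mid / 1e6, wi$count, type = "l", xlab = paste(ch, "(Mb)"),
                   ylab = "sites / window", main = x$label, ...)
    graphics::abline(h = mu, lty = 2)
    if (!is.na(sig) && sig > 0) graphics::abline(h = mu + zcrit * sig, lty = 3)
    cl <- x$clusters[x$clusters$chrom == ch, ]
    if (nrow(cl)) {
      graphics::rect(cl$start / 1e6, graphics::par("usr")[3],
                     cl$end / 1e6, graphics::par("usr")[4],
                     col = grDevices::adjustcolor("red", 0.15), border = NA)
    }
  }
  invisible(x)
}

#' Write a cluster set as BED6+1
#'
#' Columns: chrom, start, end, cluster_id, member-site count, strand
#' (`.`), cluster p-value (scientific notation, 3 significant digits).
#' Rows follow genome chromosome order, then start. An empty set yields an
#' empty file.
#'
#' @param clusters a [cluster_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (nrow(clusters) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  df <- data.frame(clusters$chrom, fmt_coord(clusters$start),
                   fmt_coord(clusters$end), clusters$cluster_id,
                   clusters$n_sites, ".",
                   formatC(clusters$p_value, format = "e", digits = 3))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a cluster BED (as written by [write_clusters()])
#'
#' Member site ids are not stored in BED and come back empty.
#'
#' @param path path to a BED6+1 cluster file (BED3 accepted; missing
#'   columns are filled with defaults).
#' @param label set label.
#' @param genome optional [genome_layout()] used to order clusters.
#' @return A [cluster_set()].
#' @export
read_clusters <- function(path, label, genome = NULL) {
  if (!file.exists(path)) stopf("cluster file not found: %s", path)
  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines == 0L) {
    return(cluster_set(NULL, label = label, genome = genome))
  }
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  clusters <- data.frame(
    cluster_id = if (ncol(df) >= 4) as.character(df[[4]]) else paste0(label, "_c", seq_len(nrow(df))),
    chrom = as.character(df[[1]]),
    start = as.numeric(df[[2]]), end = as.numeric(df[[3]]),
    n_sites = if (ncol(df) >= 5) as.integer(df[[5]]) else NA_integer_,
    p_value = if (ncol(df) >= 7) as.numeric(df[[7]]) else NA_real_,
    n_windows_merged = NA_integer_, stringsAsFactors = FALSE)
  cluster_set(clusters, member_site_ids = rep(list(character(0)), nrow(df)),
              label = label, genome = genome)
}
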