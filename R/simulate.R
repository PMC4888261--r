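#' Simulation configuration
#'
#' Describes a synthetic genome and site sets with the statistical
#' structure the scan assumes: background genes of which a fixed fraction
#' sit inside multi-megabase "clumps" (the genome's inherent gene
#' clustering), and DMR sites optionally enriched inside those clumps
#' and/or inside explicitly planted regions with a known density fold.
#'
#' Defaults emulate a desk-scale version of a mammalian study genome:
#' four 50 Mb chromosomes, 3,000 annotated genes of which one third lie
#' in 20 clumps of 2-5 Mb, and 1,000 DMR sites placed half inside clumps.
#'
#' @param n_chromosomes number of chromosomes (named `chr1..chrN`).
#' @param chrom_length length of every chromosome in bp.
#' @param n_background_genes number of background (annotation) genes.
#' @param clump_fraction fraction of genes placed inside clumps (the
#'   classical figure is about one third of known genes).
#' @param n_clumps number of non-overlapping clump intervals.
#' @param clump_length length-2 numeric range (bp) from which each
#'   clump's length is drawn uniformly.
#' @param n_dmr number of DMR sites (before planted extras).
#' @param dmr_in_clump_fraction fraction of DMRs placed inside gene
#'   clumps.
#' @param planted_regions `NULL` or a data frame with columns `chrom`,
#'   `start`, `end`, `fold` (`fold >= 1`): regions whose final DMR density
#'   is `fold` times the uniform expectation, achieved by adding extra
#'   sites on top of the uniform background.
#' @param seed integer seed; every draw is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 4, chrom_length = 50e6,
                       n_background_genes = 3000, clump_fraction = 1 / 3,
                       n_clumps = 20, clump_length = c(2e6, 5e6),
                       n_dmr = 1000, dmr_in_clump_fraction = 0.5,
                       planted_regions = NULL, seed = 1) {
  if (!is_whole(n_chromosomes) || n_chromosomes < 1) {
    stopf("n_chromosomes must be a positive integer")
  }
  stopifnot(is_whole(chrom_length), chrom_length > 0,
            is_whole(n_background_genes), n_background_genes >= 0,
            clump_fraction >= 0, clump_fraction <= 1,
            is_whole(n_clumps), n_clumps >= 0,
            length(clump_length) == 2, all(clump_length > 0),
            clump_length[1] <= clump_length[2],
            is_whole(n_dmr), n_dmr >= 0,
            dmr_in_clump_fraction >= 0, dmr_in_clump_fraction <= 1,
            is_whole(seed))
  if (clump_length[2] > chrom_length) {
    stopf("clump_length may not exceed chrom_length")
  }
  if (!is.null(planted_regions)) {
    planted_regions <- as.data.frame(planted_regions)
    stopifnot(all(c("chrom", "start", "end", "fold") %in% names(planted_regions)))
    if (any(planted_regions$fold < 1)) stopf("planted fold must be >= 1")
    if (any(planted_regions$start < 0 | planted_regions$end > chrom_length |
              planted_regions$start >= planted_regions$end)) {
      stopf("planted regions must lie within genome bounds")
    }
    ok_chr <- planted_regions$chrom %in% paste0("chr", seq_len(n_chromosomes))
    if (!all(ok_chr)) stopf("planted region on unknown chromosome")
  }
  structure(list(n_chromosomes = n_chromosomes, chrom_length = chrom_length,
                 n_background_genes = n_background_genes,
                 clump_fraction = clump_fraction, n_clumps = n_clumps,
                 clump_length = clump_length, n_dmr = n_dmr,
                 dmr_in_clump_fraction = dmr_in_clump_fraction,
                 planted_regions = planted_regions, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a genome layout
#'
#' @param config a [sim_config()].
#' @return A [genome_layout()] of `n_chromosomes` chromosomes named
#'   `chr1..chrN`, each of `chrom_length` bp.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genome_layout(paste0("chr", seq_len(config$n_chromosomes)),
                rep(config$chrom_length, config$n_chromosomes))
}

# uniform integer positions over the whole genome; returns chrom + pos,
# leaving `margin` bp free at each chromosome end for the site interval
runif_positions <- function(genome, n, margin) {
  w <- genome$length - margin
  ci <- sample.int(nrow(genome), n, replace = TRUE, prob = w)
  pos <- floor(stats::runif(n, min = 0, max = w[ci]))
  list(chrom = genome$chrom[ci], pos = pos)
}

# non-overlapping clump placement by bounded rejection sampling
place_clumps <- function(genome, n_clumps, clump_length, max_retry = 1000L) {
  chroms <- character(n_clumps)
  starts <- ends <- numeric(n_clumps)
  for (k in seq_len(n_clumps)) {
    placed <- FALSE
    for (try in seq_len(max_retry)) {
      len <- floor(stats::runif(1, clump_length[1], clump_length[2] + 1))
      ci <- sample.int(nrow(genome), 1, prob = genome$length)
      L <- genome$length[ci]
      if (L < len) next
      s <- floor(stats::runif(1, 0, L - len + 1))
      e <- s + len
      prev <- which(chroms[seq_len(k - 1)] == genome$chrom[ci])
      if (!any(ivl_overlap(s, e, starts[prev], ends[prev]))) {
        chroms[k] <- genome$chrom[ci]; starts[k] <- s; ends[k] <- e
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stopf("could not place %d non-overlapping clumps after %d retries",
            n_clumps, max_retry)
    }
  }
  data.frame(chrom = chroms, start = starts, end = ends,
             stringsAsFactors = FALSE)
}

# positions uniform inside a set of intervals, interval chosen prop. to length
positions_in_intervals <- function(intervals, n, margin) {
  w <- pmax(intervals$end - intervals$start - margin, 1)
  ki <- sample.int(nrow(intervals), n, replace = TRUE, prob = w)
  pos <- intervals$start[ki] + floor(stats::runif(n, 0, w[ki]))
  list(chrom = intervals$chrom[ki], pos = pos)
}

#' Simulate clumped background genes
#'
#' Places `n_clumps` non-overlapping clump intervals uniformly on the
#' genome, then `round(clump_fraction * n)` genes uniformly inside clumps
#' (clump chosen proportional to its length) and the remainder uniformly
#' genome-wide. The per-category counts are deterministic (rounding, with
#' the remainder going to the uniform pool), so the clumped fraction is
#' exact and testable. Genes are emitted as 1 kb intervals.
#'
#' @param genome a [genome_layout()] (typically [simulate_genome()]).
#' @param config a [sim_config()].
#' @param label site-set label (default `"BKG"`).
#' @return List with `sites` (a [site_set()]) and `truth` (a `sim_truth`:
#'   `clumps` data frame, `planted_regions`, and per-site `provenance`
#'   factor with levels uniform/clump/planted).
#' @export
simulate_background_genes <- function(genome, config, label = "BKG") {
  stopifnot(inherits(config, "sim_config"), inherits(genome, "genome_layout"))
  set.seed(config$seed)
  gene_len <- 1000
  n <- config$n_background_genes
  clumps <- if (config$n_clumps > 0) {
    place_clumps(genome, config$n_clumps, config$clump_length)
  } else {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  }
  n_clumped <- if (nrow(clumps)) round(config$clump_fraction * n) else 0L
  n_uniform <- n - n_clumped

  chrom <- character(0); pos <- numeric(0); prov <- character(0)
  if (n_clumped > 0) {
    pc <- positions_in_intervals(clumps, n_clumped, gene_len)
    chrom <- c(chrom, pc$chrom); pos <- c(pos, pc$pos)
    prov <- c(prov, rep("clump", n_clumped))
  }
  if (n_uniform > 0) {
    pu <- runif_positions(genome, n_uniform, gene_len)
    chrom <- c(chrom, pu$chrom); pos <- c(pos, pu$pos)
    prov <- c(prov, rep("uniform", n_uniform))
  }

  ids <- paste0(label, "_", seq_len(n))
  sites <- site_set(chrom, pos, pos + gene_len, site_id = ids, label = label,
                    site_type = "gene", genome = genome)
  truth <- structure(list(clumps = clumps, planted_regions = NULL,
                          provenance = stats::setNames(
                            factor(prov, levels = c("uniform", "clump", "planted")),
                            ids)),
                     class = "sim_truth")
  list(sites = sites, truth = truth)
}

#' Simulate DMR sites with clump association and planted enrichment
#'
#' `round(dmr_in_clump_fraction * n_dmr)` DMRs are placed uniformly inside
#' the background gene clumps; the rest uniformly across the genome. For
#' each planted region the uniform allocation inside the region is fixed
#' at its rounded expectation `round(n_uniform * len / G)` and
#' `round(fold * n_uniform * len / G) - round(n_uniform * len / G)` extra
#' sites (provenance `"planted"`) are added, so the number of sites inside
#' the region equals `round(fold * n_uniform * len / G)` exactly. The
#' remaining uniform sites are placed outside all planted regions. DMRs
#' are emitted as 500 bp intervals.
#'
#' @param genome a [genome_layout()].
#' @param config a [sim_config()].
#' @param truth the `sim_truth` from [simulate_background_genes()];
#'   required when `dmr_in_clump_fraction > 0`.
#' @param label site-set label (default `"DMR"`).
#' @return List with `sites` and updated `truth` (planted regions and DMR
#'   provenance appended).
#' @export
simulate_dmr_sites <- function(genome, config, truth = NULL, label = "DMR") {
  stopifnot(inherits(config, "sim_config"), inherits(genome, "genome_layout"))
  # derived stream so gene and DMR placement are independently reproducible
  set.seed((config$seed + 9973L) %% .Machine$integer.max)
  dmr_len <- 500
  n <- config$n_dmr
  pr <- config$planted_regions
  G <- genome_total_length(genome)

  n_clumped <- 0L
  if (config$dmr_in_clump_fraction > 0) {
    if (is.null(truth) || nrow(truth$clumps) == 0L) {
      stopf("dmr_in_clump_fraction > 0 requires background clump truth")
    }
    n_clumped <- round(config$dmr_in_clump_fraction * n)
  }
  n_uniform <- n - n_clumped

  chrom <- character(0); pos <- numeric(0); prov <- character(0)
  if (n_clumped > 0) {
    pc <- positions_in_intervals(truth$clumps, n_clumped, dmr_len)
    chrom <- c(chrom, pc$chrom); pos <- c(pos, pc$pos)
    prov <- c(prov, rep("clump", n_clumped))
  }

  if (!is.null(pr) && nrow(pr) > 0) {
    if (any(pr$end - pr$start > config$chrom_length)) {
      stopf("planted region larger than its chromosome")
    }
    base_in <- round(n_uniform * (pr$end - pr$start) / G)
    target_in <- round(pr$fold * n_uniform * (pr$end - pr$start) / G)
    extra_in <- pmax(0, target_in - base_in)
    n_outside <- n_uniform - sum(base_in)
    if (n_outside < 0) stopf("planted regions absorb more than the uniform pool")
    for (r in seq_len(nrow(pr))) {
      n_r <- base_in[r] + extra_in[r]
      if (n_r > 0) {
        reg <- pr[r, , drop = FALSE]
        pi <- positions_in_intervals(
          data.frame(chrom = reg$chrom, start = reg$start, end = reg$end),
          n_r, dmr_len)
        chrom <- c(chrom, pi$chrom); pos <- c(pos, pi$pos)
        prov <- c(prov, rep(c("uniform", "planted"), c(base_in[r], extra_in[r])))
      }
    }
    # uniform sites outside all planted regions (rejection sampling;
    # planted regions are a small fraction of the genome)
    got <- 0L
    while (got < n_outside) {
      pu <- runif_positions(genome, (n_outside - got) * 2L + 10L, dmr_len)
      mid <- pu$pos + dmr_len %/% 2
      inside <- rep(FALSE, length(mid))
      for (r in seq_len(nrow(pr))) {
        inside <- inside | (pu$chrom == pr$chrom[r] & mid >= pr$start[r] &
                              mid < pr$end[r])
      }
      keep <- which(!inside)
      keep <- keep[seq_len(min(length(keep), n_outside - got))]
      chrom <- c(chrom, pu$chrom[keep]); pos <- c(pos, pu$pos[keep])
      prov <- c(prov, rep("uniform", length(keep)))
      got <- got + length(keep)
    }
  } else if (n_uniform > 0) {
    pu <- runif_positions(genome, n_uniform, dmr_len)
    chrom <- c(chrom, pu$chrom); pos <- c(pos, pu$pos)
    prov <- c(prov, rep("uniform", n_uniform))
  }

  ids <- paste0(label, "_", seq_along(chrom))
  sites <- site_set(chrom, pos, pos + dmr_len, site_id = ids, label = label,
                    site_type = "dmr", genome = genome)
  prov_f <- stats::setNames(
    factor(prov, levels = c("uniform", "clump", "planted")), ids)
  if (is.null(truth)) {
    truth <- structure(list(clumps = data.frame(chrom = character(0),
                                                start = numeric(0),
                                                end = numeric(0)),
                            planted_regions = pr, provenance = prov_f),
                       class = "sim_truth")
  } else {
    truth$planted_regions <- pr
    truth$provenance <- c(truth$provenance, prov_f)
  }
  list(sites = sites, truth = truth)
}

#' Evaluate recovery of planted regions by called clusters
#'
#' A planted region counts as recovered when some called cluster reaches
#' an interval Jaccard index of at least `jaccard_min` with it. Recall is
#' the fraction of planted regions recovered; precision is the fraction of
#' called clusters matched to some planted region. With no called
#' clusters precision is reported as 1 by convention and flagged.
#'
#' @param called a [cluster_set()].
#' @param truth a `sim_truth` with `planted_regions`.
#' @param jaccard_min Jaccard threshold in (0, 1\].
#' @return List with `recall`, `precision`, `matches` (one row per planted
#'   region: best cluster and Jaccard), and `empty_called`.
#' @export
evaluate_recovery <- function(called, truth, jaccard_min = 0.5) {
  stopifnot(inherits(called, "cluster_set"), jaccard_min > 0, jaccard_min <= 1)
  pr <- truth$planted_regions
  n_planted <- if (is.null(pr)) 0L else nrow(pr)
  n_called <- nrow(called)
  if (n_planted == 0L) {
    return(list(recall = NA_real_,
                precision = if (n_called == 0L) 1 else 0,
                matches = NULL, empty_called = n_called == 0L))
  }
  best_j <- numeric(n_planted)
  best_cl <- rep(NA_character_, n_planted)
  matched_cl <- logical(n_called)
  for (r in seq_len(n_planted)) {
    if (n_called == 0L) next
    js <- vapply(seq_len(n_called), function(i) {
      interval_jaccard(called$chrom[i], called$start[i], called$end[i],
                       pr$chrom[r], pr$start[r], pr$end[r])
    }, numeric(1))
    best_j[r] <- max(js)
    if (best_j[r] > 0) best_cl[r] <- called$cluster_id[which.max(js)]
    matched_cl <- matched_cl | (js >= jaccard_min)
  }
  recovered <- best_j >= jaccard_min
  list(recall = mean(recovered),
       precision = if (n_called == 0L) 1 else mean(matched_cl),
       matches = data.frame(chrom = pr$chrom, start = pr$start, end = pr$end,
                            fold = pr$fold, best_cluster = best_cl,
                            jaccard = best_j, recovered = recovered,
                            stringsAsFactors = FALSE),
       empty_called = n_called == 0L)
}

#' Write simulation truth as JSON
#'
#' @param truth a `sim_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  obj <- list(
    clumps = truth$clumps,
    planted_regions = truth$planted_regions,
    provenance = as.list(stats::setNames(as.character(truth$provenance),
                                         names(truth$provenance))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns", pretty = TRUE)
  invisible(path)
}
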