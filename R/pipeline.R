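#' Summary table of cluster sets (one row per dataset)
#'
#' For each labeled dataset: total sites, total clusters, sites inside
#' clusters, and the percentage of sites in clusters, rounded to the
#' nearest integer (half away from zero) with the unrounded value kept in
#' a parallel column.
#'
#' @param cluster_sets named list of [cluster_set()]s.
#' @param site_sets named list of [site_set()]s with matching names.
#' @return Data frame with columns `label`, `n_sites`, `n_clusters`,
#'   `n_sites_in_clusters`, `percent_in_clusters`, `percent_exact`,
#'   `data_type`, in the order of `cluster_sets`.
#' @export
summarize_clusters <- function(cluster_sets, site_sets) {
  labs <- names(cluster_sets)
  if (is.null(labs) || !setequal(labs, names(site_sets))) {
    stopf("cluster_sets and site_sets must be named lists with matching labels")
  }
  rows <- lapply(labs, function(lb) {
    ss <- site_sets[[lb]]
    cs <- cluster_sets[[lb]]
    pic <- percent_in_clusters(ss, cs)
    data.frame(label = lb, n_sites = nrow(ss), n_clusters = nrow(cs),
               n_sites_in_clusters = pic$n_in,
               percent_in_clusters = as.integer(round_half_up(pic$percent)),
               percent_exact = pic$percent,
               data_type = switch(attr(ss, "site_type"),
                                  gene = "Differential Gene Expression",
                                  dmr = "Differential DNA Methylation"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pipeline configuration
#'
#' @param genome path to a chrom.sizes file.
#' @param datasets data frame (or list coercible to one) with columns
#'   `label`, `path`, `site_type` — one row per input BED site list.
#' @param background optional path to a BED of all annotated genes, from
#'   which background clusters are called and subtracted.
#' @param params a [scan_params()].
#' @param out_dir output directory (created if missing).
#' @param point_rule representative-point rule for all site sets.
#' @param seed recorded in the log (the scan itself is deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genome, datasets, background = NULL,
                            params = scan_params(), out_dir,
                            point_rule = "midpoint", seed = 1L) {
  datasets <- as.data.frame(datasets, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "path", "site_type") %in% names(datasets)),
            nrow(datasets) >= 1)
  if (anyDuplicated(datasets$label)) stopf("dataset labels must be unique")
  missing <- c(genome, datasets$path, background)
  missing <- missing[!file.exists(missing)]
  if (length(missing)) {
    stopf("input file(s) not found: %s", paste(missing, collapse = ", "))
  }
  structure(list(genome = genome, datasets = datasets,
                 background = background, params = params,
                 out_dir = out_dir, point_rule = point_rule,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror [pipeline_config()]: `genome`, `datasets` (list
#' of `{label, path, site_type}`), optional `background`, optional
#' `params` (keys of [scan_params()]), `out_dir`, `point_rule`, `seed`.
#' Relative paths are resolved against the YAML file's directory.
#'
#' @param path path to the YAML config.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  ds <- do.call(rbind, lapply(cfg$datasets, function(d) {
    data.frame(label = d$label, path = resolve(d$path),
               site_type = d$site_type, stringsAsFactors = FALSE)
  }))
  par_args <- cfg$params
  params <- if (is.null(par_args)) scan_params() else do.call(scan_params, par_args)
  pipeline_config(genome = resolve(cfg$genome), datasets = ds,
                  background = resolve(cfg$background), params = params,
                  out_dir = resolve(cfg$out_dir),
                  point_rule = if (is.null(cfg$point_rule)) "midpoint" else cfg$point_rule,
                  seed = if (is.null(cfg$seed)) 1L else cfg$seed)
}

write_windows_tsv <- function(windows, path) {
  df <- windows
  df$start <- fmt_coord(df$start)
  df$end <- fmt_coord(df$end)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full cluster-analysis pipeline
#'
#' For every dataset: scan, write `<label>_windows.tsv` and
#' `<label>_clusters.bed`. If a background gene annotation is configured:
#' call background clusters with the same scan parameters, write
#' `bkg_clusters.bed`, subtract them from every dataset's clusters
#' (writing `<label>_retained.bed` / `<label>_removed.bed`), and write two
#' overlap matrices — all cluster sets plus background
#' (`overlap_matrix.tsv`), and the retained sets after subtraction
#' (`overlap_matrix_nobkg.tsv`). Always writes `summary.tsv`, a plain-text
#' `run.log` (parameters, seed, package version, input digests,
#' dropped-site counts), and a `DONE` sentinel on success; a missing
#' sentinel flags a partial run.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @return The output directory, invisibly. The returned directory also
#'   carries the in-memory results as the attribute `"results"` (list with
#'   `scans`, `cluster_sets`, `site_sets`, `summary`, matrices, and
#'   subtraction results).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  done_file <- file.path(out, "DONE")
  if (file.exists(done_file)) file.remove(done_file)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  stage <- "read_genome"
  result <- tryCatch({
    genome <- read_genome(config$genome)
    say("genome: %s (%d chromosomes, %s bp)", config$genome, nrow(genome),
        fmt_coord(genome_total_length(genome)))
    say("params: window=%s step=%s alpha=%g merge_gap=%s null_scope=%s sd_mode=%s mt=%s",
        fmt_coord(config$params$window_size), fmt_coord(config$params$step),
        config$params$alpha, fmt_coord(config$params$merge_gap),
        config$params$null_scope, config$params$sd_mode,
        config$params$mt_correction)
    say("seed: %d; ecrscan version: %s; R version: %s", config$seed,
        as.character(utils::packageVersion("ecrscan")), R.version.string)
    for (f in c(config$genome, config$datasets$path, config$background)) {
      say("input digest: %s %s", unname(tools::md5sum(f)), f)
    }

    stage <- "read_sites"
    site_sets <- list()
    for (i in seq_len(nrow(config$datasets))) {
      d <- config$datasets[i, ]
      ss <- read_sites(d$path, label = d$label, site_type = d$site_type,
                       genome = genome, point_rule = config$point_rule)
      say("dataset %s: %d sites read from %s (%d dropped off-genome)",
          d$label, nrow(ss), d$path, attr(ss, "n_dropped"))
      site_sets[[d$label]] <- ss
    }

    stage <- "scan"
    scans <- list()
    cluster_sets <- list()
    for (lb in names(site_sets)) {
      sc <- cluster_scan(site_sets[[lb]], genome, config$params)
      scans[[lb]] <- sc
      cluster_sets[[lb]] <- sc$clusters
      write_windows_tsv(sc$windows, file.path(out, paste0(lb, "_windows.tsv")))
      write_clusters(sc$clusters, file.path(out, paste0(lb, "_clusters.bed")))
      say("scan %s: %d windows, %d clusters, %d sites in clusters", lb,
          nrow(sc$windows), nrow(sc$clusters), sum(sc$clusters$n_sites))
    }

    bkg_scan <- NULL
    subtractions <- NULL
    m_with <- m_without <- NULL
    if (!is.null(config$background)) {
      stage <- "background"
      bkg_sites <- read_sites(config$background, label = "BKG",
                              site_type = "gene", genome = genome,
                              point_rule = config$point_rule)
      say("background: %d gene sites read from %s (%d dropped)",
          nrow(bkg_sites), config$background, attr(bkg_sites, "n_dropped"))
      bkg_scan <- cluster_scan(bkg_sites, genome, config$params)
      write_clusters(bkg_scan$clusters, file.path(out, "bkg_clusters.bed"))
      say("background clusters: %d", nrow(bkg_scan$clusters))
      site_sets[["BKG"]] <- bkg_sites

      stage <- "subtract_background"
      subtractions <- list()
      for (lb in names(cluster_sets)) {
        sub <- subtract_background(cluster_sets[[lb]], bkg_scan$clusters)
        subtractions[[lb]] <- sub
        write_clusters(sub$retained, file.path(out, paste0(lb, "_retained.bed")))
        write_clusters(sub$removed, file.path(out, paste0(lb, "_removed.bed")))
        say("subtract %s: %d retained, %d removed of %d", lb,
            sub$n_retained, sub$n_removed, sub$n_input)
      }

      stage <- "overlap_matrix"
      m_with <- overlap_matrix(c(cluster_sets, list(BKG = bkg_scan$clusters)),
                               labels = c(names(cluster_sets), "BKG"))
      write_overlap_matrix(m_with, file.path(out, "overlap_matrix.tsv"))
      retained_sets <- lapply(subtractions, function(s) s$retained)
      m_without <- overlap_matrix(retained_sets, labels = names(retained_sets))
      write_overlap_matrix(m_without, file.path(out, "overlap_matrix_nobkg.tsv"))
    } else {
      stage <- "overlap_matrix"
      m_with <- overlap_matrix(cluster_sets, labels = names(cluster_sets))
      write_overlap_matrix(m_with, file.path(out, "overlap_matrix.tsv"))
    }

    stage <- "summarize"
    summary_sets <- cluster_sets
    if (!is.null(bkg_scan)) summary_sets[["BKG"]] <- bkg_scan$clusters
    smry <- summarize_clusters(summary_sets, site_sets[names(summary_sets)])
    if (!is.null(bkg_scan)) {
      smry$data_type[smry$label == "BKG"] <- "Locations of All Genes"
    }
    utils::write.table(smry, file.path(out, "summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    writeLines(log, file.path(out, "run.log"))
    writeLines("ok", done_file)
    list(scans = scans, cluster_sets = cluster_sets, site_sets = site_sets,
         summary = smry, overlap_with_bkg = m_with,
         overlap_without_bkg = m_without, subtractions = subtractions,
         bkg_scan = bkg_scan)
  }, error = function(e) {
    writeLines(c(log, sprintf("FAILED at stage %s: %s", stage,
                              conditionMessage(e))),
               file.path(out, "run.log"))
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })

  invisible(structure(out, results = result))
}
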