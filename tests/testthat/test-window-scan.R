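test_that("window tiling covers each chromosome with full-length windows", {
  p <- scan_params()
  w <- make_windows(tg(c(chr1 = 5e6)), p)
  expect_identical(nrow(w), 61L)
  expect_identical(w$start[1], 0)
  expect_identical(w$start[61], 3e6)
  expect_true(all(w$end - w$start == 2e6))

  # chromosome shorter than the window: one window spanning it
  w1 <- make_windows(tg(c(chrS = 1e6)), p)
  expect_identical(nrow(w1), 1L)
  expect_identical(c(w1$start, w1$end), c(0, 1e6))

  # final right-anchored window inserted when the last step overshoots
  w2 <- make_windows(tg(c(chrX = 2025000)), p)
  expect_identical(w2$start, c(0, 25000))
  expect_true(all(w2$end - w2$start == 2e6))

  # multi-chromosome tiling preserves genome order
  wm <- make_windows(tg(c(chr2 = 3e6, chr1 = 5e6)), p)
  expect_identical(unique(wm$chrom), c("chr2", "chr1"))
})

test_that("window counts respect half-open boundaries and overlap multiplicity", {
  g <- tg(c(chr1 = 4e6))
  s <- site_set("chr1", c(150, 1999999, 2000000), c(151, 2000000, 2000001),
                site_id = c("a", "b", "c"), label = "B", site_type = "dmr",
                genome = g, point_rule = "start")
  w <- data.frame(chrom = "chr1", start = c(0, 1950000), end = c(2e6, 3950000))
  cw <- count_in_windows(w, s)
  expect_identical(cw$count, c(2L, 2L))  # b in both; c only in the second

  # a point inside k overlapping windows is counted k times
  p <- scan_params(window_size = 2e6, step = 5e5)
  wins <- make_windows(g, p)
  one <- site_set("chr1", 2100000, 2100500, label = "B1", site_type = "dmr",
                  genome = g, point_rule = "start")
  cw2 <- count_in_windows(wins, one)
  covering <- wins$start <= 2100000 & wins$end > 2100000
  expect_identical(cw2$count, as.integer(covering))
})

test_that("window counts equal the exhaustive per-window oracle on random instances", {
  p <- scan_params()
  for (seed in 1:25) {
    set.seed(seed)
    n_chr <- sample(1:3, 1)
    g <- genome_layout(paste0("chr", seq_len(n_chr)),
                       sample(seq(1e6, 8e6, by = 1e6), n_chr, replace = TRUE))
    s <- uniform_sites(g, sample(10:300, 1), seed = seed + 1000)
    w <- count_in_windows(make_windows(g, p), s)
    expect_identical(as.numeric(w$count), brute_count(w, s))
  }
})

test_that("z-scores and one-sided tail probabilities match the frozen oracle values", {
  w <- data.frame(chrom = "chr1", start = 0:4 * 1e6, end = 1:5 * 1e6,
                  count = c(2, 2, 2, 2, 12))
  sc <- score_windows(w, scan_params())
  # oracle values computed independently (scipy.stats.norm)
  expect_equal(sc$windows$z[5], 1.7888543820, tolerance = 1e-9)
  expect_equal(sc$windows$p[5], 0.0368191351, tolerance = 1e-8)
  expect_lt(sc$windows$p[5], 0.05)
  expect_equal(unname(sc$null_mean["genome"]), 4)
  expect_equal(unname(sc$null_sd["genome"]), sqrt(20), tolerance = 1e-12)

  # depleted windows are never significant (one-sided upper tail)
  expect_true(all(sc$windows$p[1:4] > 0.5))

  scp <- score_windows(w, scan_params(sd_mode = "population"))
  expect_equal(scp$windows$z[5], 2, tolerance = 1e-12)
  expect_equal(scp$windows$p[5], 0.0227501319, tolerance = 1e-8)
})

test_that("degenerate and undersized nulls are handled as contracted", {
  w <- data.frame(chrom = "chr1", start = 0:3, end = 1:4, count = rep(3, 4))
  expect_warning(sc <- score_windows(w, scan_params()), "degenerate")
  expect_true(all(sc$windows$p == 1))
  expect_true(all(is.na(sc$windows$z)))

  w1 <- data.frame(chrom = "chr1", start = 0, end = 1, count = 5)
  expect_error(score_windows(w1, scan_params()), "insufficient")

  # per-chromosome scope scores each chromosome against its own null
  w2 <- data.frame(chrom = rep(c("chrA", "chrB"), each = 3),
                   start = rep(0:2, 2), end = rep(1:3, 2),
                   count = c(1, 2, 9, 5, 5, 5))
  expect_warning(
    sc2 <- score_windows(w2, scan_params(null_scope = "per_chromosome")),
    "degenerate")
  expect_length(sc2$null_mean, 2)
  expect_true(all(sc2$windows$p[4:6] == 1))  # chrB flat
  expect_lt(sc2$windows$p[3], 0.2)           # chrA peak scored on chrA null
})

test_that("significant windows merge transitively by gap, and p/min rules hold", {
  g <- tg(c(chr1 = 10e6))
  s <- site_set("chr1", c(5e5, 1e6, 2.1e6, 3e6), c(5e5, 1e6, 2.1e6, 3e6) + 100,
                label = "M", site_type = "gene", genome = g,
                point_rule = "start")
  mkscored <- function(starts, ends, p) {
    list(windows = data.frame(chrom = "chr1", start = starts, end = ends,
                              count = 0, z = 0, p = p))
  }
  par <- scan_params()

  # overlapping significant windows merge into one span
  cs <- call_clusters(mkscored(c(1e5, 1.5e5), c(2.1e6, 2.15e6), c(0.01, 0.003)),
                      s, par)
  expect_identical(nrow(cs), 1L)
  expect_identical(c(cs$start, cs$end), c(1e5, 2.15e6))
  expect_identical(cs$n_windows_merged, 2L)
  expect_equal(cs$p_value, 0.003)
  expect_identical(cs$cluster_id, "M_c1")
  expect_identical(cs$n_sites, 3L)  # points 5e5, 1e6, 2.1e6 in [1e5, 2.15e6)
  expect_identical(attr(cs, "member_site_ids")[[1]], c("M_1", "M_2", "M_3"))

  # gap exactly merge_gap merges; gap 0 splits
  two <- mkscored(c(0, 2.05e6), c(2e6, 4.05e6), c(0.01, 0.02))
  merged <- call_clusters(two, s, scan_params(merge_gap = 5e4))
  expect_identical(nrow(merged), 1L)
  expect_identical(c(merged$start, merged$end), c(0, 4.05e6))
  split <- call_clusters(two, s, scan_params(merge_gap = 0))
  expect_identical(nrow(split), 2L)

  # nothing significant -> empty set
  none <- call_clusters(mkscored(0, 2e6, 0.5), s, par)
  expect_identical(nrow(none), 0L)
})

test_that("clusters in a set are disjoint, ordered, and contain their members", {
  g <- tg(c(chr1 = 50e6, chr2 = 50e6))
  set.seed(11)
  dense1 <- floor(runif(40, 10e6, 12e6))
  dense2 <- floor(runif(40, 30e6, 31e6))
  bgpos <- floor(runif(200, 0, 50e6 - 1000))
  bgchr <- rep(c("chr1", "chr2"), 100)
  s <- site_set(c(rep("chr2", 80), bgchr), c(dense1, dense2, bgpos),
                c(dense1, dense2, bgpos) + 500, label = "D",
                site_type = "dmr", genome = g)
  res <- cluster_scan(s, g)
  cl <- res$clusters
  expect_gte(nrow(cl), 2)
  for (ch in unique(cl$chrom)) {
    cc <- cl[cl$chrom == ch, ]
    if (nrow(cc) > 1) {
      expect_true(all(cc$start[-1] >= cc$end[-nrow(cc)]))  # disjoint, sorted
    }
  }
  expect_true(all(cl$end - cl$start >= res$params$window_size))
  expect_identical(cl$n_sites,
                   lengths(attr(cl, "member_site_ids"), use.names = FALSE))
  # member counting agrees with the percentage primitive on disjoint clusters
  pic <- percent_in_clusters(s, cl)
  expect_identical(pic$n_in, sum(cl$n_sites))
})

test_that("an isolated dense region yields exactly one cluster holding all its points", {
  g <- tg(c(chr1 = 50e6))
  pos <- floor(seq(20e6, 21.9e6, length.out = 30))
  s <- site_set("chr1", pos, pos + 100, label = "ONE", site_type = "gene",
                genome = g)
  res <- cluster_scan(s, g)
  expect_identical(nrow(res$clusters), 1L)
  expect_identical(res$clusters$n_sites, 30L)
  expect_true(res$clusters$start <= 20e6 && res$clusters$end > 21.9e6)
})

test_that("an empty site set scans to an empty cluster set via the degenerate null", {
  g <- tg(c(chr1 = 10e6))
  s <- site_set(character(0), numeric(0), numeric(0), label = "E",
                site_type = "gene", genome = g)
  expect_warning(res <- cluster_scan(s, g), "degenerate")
  expect_identical(nrow(res$clusters), 0L)
  expect_true(all(res$windows$count == 0))
})

test_that("scanning is deterministic", {
  g <- tg(c(chr1 = 20e6))
  s <- uniform_sites(g, 150, seed = 3, label = "DET")
  r1 <- cluster_scan(s, g)
  r2 <- cluster_scan(s, g)
  expect_identical(r1$windows, r2$windows)
  expect_identical(as.data.frame(r1$clusters), as.data.frame(r2$clusters))
})

test_that("adding a site inside a cluster span never removes the cluster at fixed null", {
  g <- tg(c(chr1 = 20e6))
  set.seed(21)
  for (rep in 1:10) {
    s <- uniform_sites(g, 120, seed = rep, label = "MONO")
    p <- scan_params()
    w <- count_in_windows(make_windows(g, p), s)
    sc <- score_windows(w, p)
    cl <- call_clusters(sc, s, p)
    if (nrow(cl) == 0) next
    mu <- sc$null_mean[["genome"]]; sg <- sc$null_sd[["genome"]]
    # add one site inside the first cluster span, re-count, re-score at fixed null
    newpos <- floor((cl$start[1] + cl$end[1]) / 2)
    s2 <- site_set(c(s$chrom, "chr1"), c(s$start, newpos),
                   c(s$end, newpos + 100),
                   site_id = c(s$site_id, "extra"), label = "MONO",
                   site_type = "gene", genome = g)
    w2 <- count_in_windows(make_windows(g, p), s2)
    w2$z <- (w2$count - mu) / sg
    w2$p <- pnorm(w2$z, lower.tail = FALSE)
    cl2 <- call_clusters(list(windows = w2), s2, p)
    hit <- any(cl2$chrom == cl$chrom[1] &
                 pmax(cl2$start, cl$start[1]) < pmin(cl2$end, cl$end[1]))
    expect_true(hit)
  }
})

test_that("null calibration: uniform sites give a near-alpha significant-window rate", {
  frac_sig <- function(seed, step) {
    g <- genome_layout("chr1", 200e6)
    s <- uniform_sites(g, 1000, seed = seed, len = 500, site_type = "dmr")
    p <- scan_params(step = step)
    sc <- score_windows(count_in_windows(make_windows(g, p), s), p)
    mean(sc$windows$p < 0.05)
  }
  # overlapping windows are correlated, so only a loose band is expected
  f_overlap <- vapply(1:200, frac_sig, numeric(1), step = 5e4)
  expect_gte(mean(f_overlap), 0.01)
  expect_lte(mean(f_overlap), 0.10)
})

test_that("Benjamini-Hochberg correction thresholds on adjusted p-values", {
  g <- tg(c(chr1 = 100e6))
  set.seed(5)
  pos <- c(floor(runif(500, 0, 100e6 - 500)), floor(runif(40, 50e6, 52e6)))
  s <- site_set("chr1", pos, pos + 500, label = "BH", site_type = "dmr",
                genome = g)
  raw <- cluster_scan(s, g, scan_params())
  adj <- cluster_scan(s, g, scan_params(mt_correction = "bh"))
  expect_true(!is.null(adj$windows$p_adj))
  expect_true(all(adj$windows$p_adj >= adj$windows$p))
  expect_lte(nrow(adj$clusters), nrow(raw$clusters))
  # the genuinely dense region survives correction
  expect_true(any(adj$clusters$start < 52e6 & adj$clusters$end > 50e6))
})

test_that("a strongly planted region is recovered by an overlapping cluster", {
  hits <- 0L
  jac <- numeric(20)
  for (i in 1:20) {
    cfg <- sim_config(n_chromosomes = 1, chrom_length = 200e6,
                      n_background_genes = 0, clump_fraction = 0, n_clumps = 0,
                      n_dmr = 1000, dmr_in_clump_fraction = 0,
                      planted_regions = data.frame(chrom = "chr1", start = 99e6,
                                                   end = 101e6, fold = 5),
                      seed = i)
    g <- simulate_genome(cfg)
    dm <- simulate_dmr_sites(g, cfg)
    res <- cluster_scan(dm$sites, g)
    ev <- evaluate_recovery(res$clusters, dm$truth, jaccard_min = 0.25)
    jac[i] <- ev$matches$jaccard[1]
    if (ev$recall == 1) hits <- hits + 1L
  }
  # the planted region is essentially always found; the union-of-windows
  # cluster span (~region + up to one window each side) bounds the Jaccard
  expect_gte(hits, 18L)
  expect_gte(mean(jac), 0.25)
})
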