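# Fixtures are built in code; nothing is stored on disk.

tg <- function(lengths = c(chr1 = 5e6, chr2 = 3e6)) {
  genome_layout(names(lengths), unname(lengths))
}

# n sites of width `len` placed uniformly on the genome, seeded
uniform_sites <- function(genome, n, seed, len = 1000, label = "U",
                          site_type = "gene") {
  set.seed(seed)
  ci <- sample.int(nrow(genome), n, replace = TRUE, prob = genome$length)
  pos <- floor(runif(n, 0, genome$length[ci] - len))
  site_set(genome$chrom[ci], pos, pos + len, label = label,
           site_type = site_type, genome = genome)
}

# exhaustive per-window point scan: the counting oracle
brute_count <- function(windows, sites) {
  vapply(seq_len(nrow(windows)), function(i) {
    sum(sites$chrom == windows$chrom[i] &
          sites$point >= windows$start[i] &
          sites$point < windows$end[i])
  }, numeric(1))
}

# exhaustive double-loop overlap-pair matrix: the comparison oracle
brute_overlap_matrix <- function(sets, labels) {
  n <- length(sets)
  m <- matrix(0L, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    m[i, i] <- nrow(sets[[i]])
    for (j in seq_len(n)) {
      if (i >= j) next
      cnt <- 0L
      a <- sets[[i]]; b <- sets[[j]]
      for (ai in seq_len(nrow(a))) {
        for (bi in seq_len(nrow(b))) {
          if (a$chrom[ai] == b$chrom[bi] &&
              max(a$start[ai], b$start[bi]) < min(a$end[ai], b$end[bi])) {
            cnt <- cnt + 1L
          }
        }
      }
      m[i, j] <- m[j, i] <- cnt
    }
  }
  m
}

# hand-built cluster_set from interval vectors
mk_clusters <- function(chrom, start, end, label = "X", genome = NULL) {
  n <- length(start)
  cluster_set(
    data.frame(cluster_id = sprintf("%s_c%d", label, seq_len(n)),
               chrom = rep(chrom, length.out = n),
               start = start, end = end,
               n_sites = rep(0L, n), p_value = rep(NA_real_, n),
               n_windows_merged = rep(1L, n), stringsAsFactors = FALSE),
    member_site_ids = rep(list(character(0)), n),
    label = label, genome = genome)
}

# site set with exactly n_in points inside [0, 2e6) of chr1 and the rest
# spread far away; used for percentage arithmetic
sites_with_counts <- function(n_total, n_in, label, genome) {
  inside <- seq(0, 2e6 - 1000, length.out = n_in)
  outside <- seq(10e6, 90e6, length.out = n_total - n_in)
  pos <- floor(c(inside, outside))
  site_set("chr1", pos, pos + 500, label = label, site_type = "gene",
           genome = genome)
}
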