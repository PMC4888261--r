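---
title: "Sliding-window detection of gene and DMR clusters"
author: "ecrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sliding-window detection of gene and DMR clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecrscan)
```

## The problem

Differentially expressed genes and differential DNA methylation regions
(DMRs) are not scattered independently along chromosomes: both tend to
co-occur in multi-megabase neighbourhoods. Regions of 2–5 Mb carrying a
statistically over-represented number of such sites — sometimes called
epigenetic control regions (ECRs) — are candidates for regional,
epigenetically mediated co-regulation. Detecting them from a list of site
coordinates is a one-dimensional scan statistic problem: count sites in a
sliding window, ask whether any window holds more sites than a genome-wide
expectation, and merge the significant windows into contiguous clusters.

Two complications shape the design. First, genomes have *inherent* gene
clumping — clusters called from the positions of **all** annotated genes,
with no treatment contrast at all. Any cluster of differentially expressed
genes that coincides with such a background clump may simply reflect gene
density, so background clusters must be called with the same procedure and
subtracted. Second, data sets from different tissues or exposures are
compared at the cluster level, via overlap counts, not at the site level.

## The scan statistic

Each chromosome is tiled separately with windows of width $w$ (default
2 Mb) advanced in steps of $s$ (default 50 kb). Window $i$ receives the
count $c_i$ of site points falling in $[{\rm start}_i, {\rm end}_i)$; a
site interval is reduced to a representative point beforehand. With
$\mu$ and $\sigma$ the mean and standard deviation of the window counts,
each window is scored

$$ z_i = \frac{c_i - \mu}{\sigma}, \qquad
   p_i = 1 - \Phi(z_i), $$

a one-sided upper-tail z-test: only over-represented windows can be
significant, depleted windows never are. Windows with $p_i < \alpha$
(default 0.05) on the same chromosome whose intervals overlap or lie
within the merge gap (default 50 kb, i.e. consecutive steps) are merged
transitively; the cluster spans the union of its windows, carries all site
points inside that span as members, and reports the minimum constituent
window $p$ as its p-value.

`cluster_scan()` performs the whole procedure and returns a classed object
with `print()`, `summary()` and `plot()` methods:

```{r, eval = FALSE}
genome <- read_genome("rat.chrom.sizes")
dmr <- read_sites("dmr.bed", label = "DMR", site_type = "dmr",
                  genome = genome)
res <- cluster_scan(dmr, genome, scan_params())
summary(res)
write_clusters(res$clusters, "dmr_clusters.bed")
```

## Modelling choices and their rationale

The z-test needs a null mean and standard deviation, and several choices
are genuinely open; each is a `scan_params()` field so the alternative
reading is one argument away.

* **Null scope** (`null_scope`, default `"genome"`). $\mu$ and $\sigma$
  are pooled over all windows genome-wide. Pooling encodes a single global
  site density, which is the natural null for "is this region enriched
  relative to the genome"; `"per_chromosome"` instead scores each
  chromosome against its own count distribution, absorbing chromosome-scale
  density differences at the cost of power on short chromosomes.
* **Standard deviation** (`sd_mode`, default `"sample"`, $n-1$
  denominator). With thousands of windows the two estimators are
  indistinguishable; the option exists because the distinction matters in
  small synthetic examples used for verification.
* **One-sided test.** Enrichment is the phenomenon of interest; a depleted
  window (gene desert) is biologically common and uninteresting here.
* **Multiple testing** (`mt_correction`, default `"none"`). The classical
  procedure thresholds raw $p < 0.05$ per window. At ~50 kb steps a
  mammalian-scale genome yields thousands of (strongly correlated) tests,
  so roughly 5 % of windows are "significant" on uniformly scattered
  sites and *some* clusters will always be called; this is exactly why
  inherent background clusters exist and must be subtracted rather than
  wished away. A Benjamini–Hochberg option is provided for genome-wide
  error control in modern use; under it uniform data yield almost no
  clusters, at the price of a stricter effective count threshold.
* **Window tiling.** All windows are full length. If the last regular
  start does not land exactly at $L - w$, a final right-anchored window
  $[L-w, L)$ is added; truncating trailing windows instead would
  systematically depress their counts and contaminate the shared null.
  A chromosome shorter than $w$ becomes a single whole-chromosome window.
* **Degenerate null.** If $\sigma = 0$ (e.g. an empty site set) every
  p-value is set to 1 with a warning — no cluster can be called, which is
  the only defensible answer.
* **Cluster p-value.** The minimum window $p$ among the merged windows. A
  merged cluster has no single canonical p-value; min-p is reported and
  labelled as such in the BED output rather than pretending to a
  cluster-level test.
* **Representative point** (`point_rule`, default `"midpoint"`). Sites are
  intervals but are counted as points. The midpoint is symmetric, and with
  2 Mb windows dwarfing gene spans the choice is second-order; `"start"`
  covers annotations keyed to transcription starts or probe positions.

Coordinates are 0-based half-open (BED convention) everywhere; abutting
intervals do not overlap, and a point at a window's end coordinate belongs
to the next window.

## Background subtraction and overlap analysis

`subtract_background()` removes a target cluster **whole** when it shares
at least 1 bp with any background cluster — clusters are removed, never
trimmed, so the retained set is a subset of the input and the operation is
idempotent. An optional minimum reciprocal overlap fraction (default 0)
supports sensitivity analysis. `overlap_matrix()` counts overlapping
cluster *pairs* for each pair of sets, with set sizes on the diagonal;
pair counting preserves symmetry. `percent_in_clusters()` reports how many
sites of a set fall inside any cluster span; summary tables round the
percentage half-away-from-zero and keep the exact value in a parallel
column. The interval machinery behind these operations is GenomicRanges;
the scan statistic and merging above are implemented directly in the
package.

## The synthetic-data generator

Real inputs at study scale are site lists distilled from microarray and
MeDIP-chip experiments. The generator (`sim_config()`,
`simulate_genome()`, `simulate_background_genes()`,
`simulate_dmr_sites()`) emulates the coordinate-level structure those
lists exhibit, not the assays:

* a multi-chromosome genome of equal-length chromosomes (default
  4 × 50 Mb);
* background genes (default 3,000 emitted as 1 kb intervals) of which a
  fixed fraction — default one third, the classical figure for annotated
  genes falling in clusters — lies inside `n_clumps` non-overlapping clump
  intervals of 2–5 Mb placed uniformly, the rest uniform genome-wide;
* DMR sites (default 1,000, 500 bp intervals) with a configurable
  fraction placed inside the gene clumps, emulating the observed
  association of sperm DMR clusters with gene clusters;
* optional planted regions with an exact density fold: the uniform
  allocation inside a planted region is fixed at its rounded expectation
  and extra sites are added so the region's final count is exactly
  `round(fold × n_uniform × len/G)`.

Category counts are allocated deterministically by rounding rather than
per-site Bernoulli draws, so clumped fractions and planted folds are exact
and testable; all placement is driven by a single integer seed and is
byte-reproducible. Clump placement uses bounded rejection sampling (1,000
retries) and fails loudly when non-overlapping placement is infeasible.

What the generator does **not** emulate: chromosome length heterogeneity,
fine-scale gene-density covariates (GC, isochores), probe spacing, or any
measurement noise — sites are exact coordinates. Passing tests therefore
demonstrate the statistical behaviour of the scan on idealised coordinate
data, not robustness to upstream array artefacts.

## Validation behaviour and known limitations

The test suite exercises the scan at desk scale (single chromosomes of
up to 200 Mb, ~10³ sites, up to 200 replicates per property — sizes chosen
so the full suite runs in about a minute while estimating rates to a few
percent).

Three empirical properties are worth stating plainly:

* **Calibration.** With 1,000 sites placed uniformly on 200 Mb, the mean
  fraction of significant windows at $\alpha = 0.05$ is ≈ 0.058, for both
  non-overlapping and 50 kb-step tilings. The slight excess over $\alpha$
  comes from using the estimated $\mu,\sigma$ on right-skewed,
  Poisson-like counts; a count distribution is not normal at density
  ~10 sites/window.
* **Uniform data still yield clusters at raw thresholds.** ~4,000
  correlated windows at raw $p<0.05$ give ~200 significant windows, which
  merge into ~10–15 spurious clusters per uniform replicate. This is a
  property of the classical procedure, not a bug; it is the reason the
  background-subtraction step exists, and the `"bh"` correction suppresses
  it almost entirely.
* **Cluster spans overshoot the enriched region.** A cluster is the union
  of *full-length* significant windows, so a 2 Mb enriched region is
  typically reported as a ~4–5 Mb cluster (every window overlapping the
  region enough to cross the count threshold is included, extending up to
  ~1.5 Mb beyond each edge). Detection of a fold-5 planted region is
  essentially certain, but the interval Jaccard between the called
  cluster and the true 2 Mb region consequently saturates near 0.4, and
  increasing the fold widens — not tightens — the span. Users who need
  tight boundaries should post-process cluster spans (e.g. trim to the
  member-site extent), which the package deliberately does not do
  silently.

Other limitations: the normal approximation is poor for very sparse site
sets (a handful of sites genome-wide); p-values are not adjusted for the
overlap correlation between windows; and cluster membership is defined by
the representative point, so a site straddling a cluster edge is in or out
according to its midpoint.
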