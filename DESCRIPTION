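Package: ecrscan
Title: Sliding-Window Detection of Gene and DNA Methylation Region
    Clusters in Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects chromosomal regions with statistically
    over-represented numbers of genomic sites -- differentially expressed
    genes or differential DNA methylation regions (DMRs) -- by counting
    site positions in a sliding window (default 2 Mb, shifted 50 kb),
    standardizing each window's count against the genome-wide mean and
    standard deviation of window counts (a one-sided z-test), and merging
    significant windows into clusters. Includes subtraction of the
    genome's inherent background gene clustering, cluster-set overlap
    matrices, a seeded synthetic-data generator with planted enrichment
    for method validation, and a config-driven pipeline producing BED and
    TSV outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
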