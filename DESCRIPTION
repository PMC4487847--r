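Package: beadwell
Title: Simulation and Processing of Microwell Bead-Based Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for combinatorially barcoded, bead-based microwell
    single-cell RNA-Seq: design and validation of two-round split-pool
    barcode sets and capture primers, closed-form Poisson/binomial loading
    statistics for microwell devices, paired-read demultiplexing with
    single-mismatch barcode correction, UMI molecule counting by
    Hamming-distance and mapping-position connected-component collapse with
    cross-barcode chimera removal, cell-barcode calling by read
    downsampling and bimodal splitting, downstream cell-type separation
    statistics (bulk correlation saturation, Wilcoxon differential
    expression, CV-ratio heterogeneity, Spearman matrices, rank-based
    classifier scores), and a fully seeded synthetic experiment generator
    with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table (>= 1.14.0),
    Matrix,
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
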