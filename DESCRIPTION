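Package: splitpool
Title: Preprocessing and QC for Split-Pool Barcoded Probe-Ligation
    Single-Cell Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probe-ligation, split-pool combinatorially barcoded
    single-cell sequencing data: a ground-truthed paired-FASTQ read simulator
    (including mixed-species "barnyard" designs), four-round barcode
    demultiplexing with positional offset and mismatch tolerance, knee-point
    cell calling from ranked barcode counts, fixed-length probe assignment
    with a brute-force-verified Hamming matcher, UMI collapse into a sparse
    cell-by-gene count matrix, QC metrics (sequencing saturation curves,
    barnyard multiplet-rate estimation and correction, capture rate,
    pseudo-bulk correlation, mitochondrial and ribosomal contamination), and
    per-cell marker-set overrepresentation analysis for rare cell type
    identification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
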