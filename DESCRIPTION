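Package: panelcnv
Title: Read-Depth Copy Number Variant Detection for Targeted Gene Panels
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects copy number variants (CNVs) in deep targeted gene-panel
    sequencing data from read depth alone. Target regions are tiled with
    overlapping sliding windows, reference pools of CNV-free samples with
    similar mean depth are built from previous runs, and each query window is
    scored as the log2 ratio of its mean depth to the pool's mean depth for
    the same window (logCNR). Includes quality control of the query/pool
    match, per-gene score tables and plots, an advisory candidate flagger
    with sub-exon breakpoint refinement, and a coverage simulator with
    capture-efficiency, batch and noise structure for validation without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    Rsamtools,
    ggplot2,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
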