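Package: popcnv
Title: Population Copy Number Variation Analysis from Windowed Read Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Read-depth copy number analysis for multi-population
    resequencing cohorts. Provides GC-bias correction and diploid
    normalization of per-window depth, per-sample CNV segment calling,
    population-level CNVR construction with allele-frequency based
    type classification and silhouette/length filtering, the Vst
    differentiation statistic with an empirical top-quantile selective
    scan, interval annotation against genes and QTLs, cross-study
    overlap comparison, and a fully synthetic multi-population cohort
    simulator with planted, population-stratified copy number variants
    so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
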