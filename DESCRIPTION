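Package: cagecompare
Title: Cross-Platform CAGE and RNA-seq Comparison with Planted-Bias Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates capped-5' tag (CAGE) and RNA-seq read sets over a
    synthetic genome with the platform-specific distortions known for
    single-molecule and PCR-amplified protocols (nontemplated 5' G addition,
    fill-and-lock T-stretch start shifting, GC-dependent amplification,
    internal EcoP15I site cleavage competition, linker first-base preference,
    polyA selection, ribosomal RNA carryover), quantifies them into CTSS
    tables and gene-level count matrices, and provides the diagnostics that
    detect each mechanism: replicate reproducibility via common
    negative-binomial overdispersion, RNA-mixture linearity and effective
    mixing-ratio estimation, stratified relative-expression reports,
    single-base start-site analyses, and sample-level clustering with
    bootstrap support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
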