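Package: surprisalr
Title: Surprisal Analysis of Bulk Transcript Expression Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Information-theoretic (surprisal) analysis of gene-by-sample
    FPKM matrices. Decomposes the natural-log expression matrix by singular
    value decomposition into a balance state common to all samples plus
    constraints whose per-sample Lagrange multipliers separate phenotype
    groups. Includes set-ratio pathway enrichment on the constraint weight
    vectors, top-contributing gene lists, stratified-subsampling robustness
    analysis with sign reattribution, K-means (Pearson distance)
    cross-validation of gene rankings, and a synthetic-data generator with
    planted low-rank structure and pathway enrichment for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
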