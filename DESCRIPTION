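Package: stromascape
Title: Stromal Compartment Gene Signatures and Prognostic Evaluation in
    Colorectal Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives tumor-microenvironment gene signatures from paired
    micro-dissected cancer-stroma/epithelium expression profiles and
    evaluates their prognostic impact in bulk-tumor survival cohorts.
    Implements single-probe housekeeping normalization, stroma/epithelium
    specificity (cS/E) ratios with High/Middle/Low classification,
    anchor-marker co-expression signature derivation by correlation
    (R-index) with abundance filtering, probe-to-symbol collapsing,
    signature overlap classification, and per-gene survival analysis
    (rank-statistic AUC for death prediction, Youden-optimal expression
    cutoffs, Kaplan-Meier estimation, log-rank tests, Cox proportional
    hazards, and two-gene combined stratification). A seeded synthetic-data
    generator plants co-expression factors, compartment specificity, and
    log-linear hazards so every pipeline stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
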