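Package: agingscreen
Title: Age-Correlated Gene Screening, Syntropy and Rescue Analysis for
    Bulk Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated pipeline for studying transcriptome aging in
    multi-tissue bulk expression cohorts. Screens genes whose expression
    correlates with donor age (Pearson correlation with t-based p-values,
    direction-specific significance thresholds), compares tissues by the
    similarity of their aging signatures and groups them by hierarchical
    clustering, intersects per-tissue calls into group aging-gene sets,
    quantifies syntropic deregulation of aging genes in disease cohorts and
    their reversal ("rescue") under anti-aging interventions such as
    physical activity, estimates cell-type fractions from bulk profiles by
    non-negative least squares against a single-cell-derived signature
    matrix, and tests gene sets for over-representation with the
    hypergeometric distribution. A synthetic-data module generates
    multi-tissue aging cohorts, case/control cohorts, intervention cohorts
    and cell mixtures with planted, machine-readable ground truth so every
    stage is testable end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
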