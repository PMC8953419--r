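Package: m6Ascore
Title: m6A Modification Pattern Scoring and Tumor Stratification
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify N6-methyladenosine (m6A) modification patterns
    in bulk tumor expression cohorts. Implements resampling consensus
    clustering of an m6A writer/eraser/reader regulator panel, pairwise
    cluster differential expression with core-DEG extraction, a weighted
    regulator signature and the m6Avalue per-sample score (sum of z-scores of
    prognostic risk genes minus sum of z-scores of protective genes),
    single-sample rank-based gene-set enrichment for immune and stromal
    signatures, Cox proportional-hazards screening, Kaplan-Meier/log-rank
    analysis with a maximally selected rank-statistic cutpoint, ROC/AUC, and
    a Spearman drug-sensitivity screen. Ships a negative-binomial cohort
    simulator with planted cluster, survival and microenvironment structure
    so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    data.table,
    jsonlite,
    matrixStats
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
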