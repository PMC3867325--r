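Package: survcutoff
Title: Cutoff-Optimized Survival Biomarker Validation Across Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for validating prognostic biomarkers in
    multi-cohort gene-expression data with clinical follow-up. Integrates
    probe-by-sample intensity matrices across array platforms on their common
    probe set, applies array-level quality-control rules and a second-stage
    scaling normalization, detects duplicated arrays by rank correlation, and
    assesses single probes, genes, or metagene signatures by percentile
    cutoff-optimized Kaplan-Meier / Cox proportional-hazards analysis with a
    univariate-to-multivariate validation workflow and per-dataset funnel
    meta-analysis. Ships a proportional-hazards simulator with planted effects
    so the whole pipeline is testable without external cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
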