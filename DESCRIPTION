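Package: txpredict
Title: Transcriptome-Guided Drug Prediction and Molecular Tumor Board Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for expression-based drug repositioning in a molecular
    tumor board workflow. A tumor expression profile is standardized against
    a whole-body panel of normal tissues to per-gene Z-scores, and five
    scoring engines (biomarker rules, drug target overexpression,
    hypergeometric hidden-node network enrichment, Connectivity-Map-style
    rank statistics, and parametric gene set enrichment against
    drug-sensitivity signatures) produce a ranked drug-prediction report.
    Tumor board decision rules convert the report into a treatment plan of
    at most four FDA-approved, pediatrically dosed agents. Companion tools
    cover sample quality-control gates, study feasibility and response
    tallies, replicate-biopsy concordance via distance-based permutational
    multivariate analysis of variance (PERMANOVA), principal coordinates
    analysis, drug-set reproducibility sweeps, and cross-platform
    (microarray versus RNA-seq) agreement statistics. A synthetic-data
    module generates every input with the statistical structure the
    analyses assume, so the full pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
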