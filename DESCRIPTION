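Package: netdyn
Title: Dynamic Functional Network Analysis via Temporal Co-Occurrence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Sliding-window dynamic functional connectivity analysis for
    node-level brain network time series. Implements exponentially weighted
    sliding-window correlation, signed-weighted Louvain community detection
    per window, temporal co-occurrence (module-allegiance) matrices, three
    node-level dynamics metrics (temporal flexibility, spatiotemporal
    diversity, within-community centrality), phase-randomization and
    degree/strength-preserving random-graph null models, and cross-validated
    canonical correlation with permutation inference for brain-behavior
    prediction. Includes a synthetic-data generator with planted community
    structure, planted flexible nodes, twin sessions, and planted
    brain-behavior coupling so every stage can be validated against ground
    truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
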