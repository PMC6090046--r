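Package: megfocus
Title: Interictal MEG Metrics for Epileptogenic-Zone Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Source-space analysis pipeline for localizing the epileptogenic
    zone from interictal MEG virtual-electrode time series on the 90-region
    AAL atlas. Computes four region-level metrics (relative delta power,
    low-to-high frequency power ratio, mean phase lag index, and minimum
    spanning tree betweenness centrality), tests the overlap of the
    highest-valued regions with the surgical resection against a
    hypergeometric chance model, compares surgery-outcome groups with
    chi-square and pooled t-tests under false-discovery-rate correction, and
    evaluates individual-level classification (linear SVM and random forest)
    of resected regions and of surgery outcome with class-balanced
    subsampling and leave-one-out cross-validation. Includes a synthetic
    cohort generator that injects focal delta-power and phase-coupling
    effects so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    e1071,
    randomForest,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
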