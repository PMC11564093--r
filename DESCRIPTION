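Package: agewave
Title: Nonlinear Trajectory and Wave Analysis for Longitudinal Multi-Omics Aging Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects nonlinear age-associated changes in longitudinal
    multi-omics cohorts. Aggregates per-visit measurements into a
    confounder-adjusted cross-sectional matrix, scans for linearly
    changing features (Spearman correlation with permutation nulls),
    quantifies stage-wise dysregulation relative to a young baseline,
    clusters LOESS-smoothed trajectories by fuzzy c-means with
    centroid-distance model selection and correlation-based cluster
    merging, locates waves of dysregulation with a sliding-window
    differential-expression statistic (modified DE-SWAN) including crest
    calling against an age-permutation envelope, and collapses pathway
    enrichments into non-redundant functional modules via Wang/Jaccard
    similarity networks and edge-betweenness communities. Ships a
    synthetic-cohort generator with planted trajectory archetypes so
    every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    data.table,
    e1071,
    igraph,
    fgsea,
    mixOmics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
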