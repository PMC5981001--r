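Package: optiongen
Title: Fluency, Uniqueness and Diversity Scoring for Freely Drawn Movement Paths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing option-generation drawing tasks in which
    participants draw as many different paths as they can between two fixed
    points on a touchscreen within a time budget. Implements arc-length
    resampling of raw trajectories, a mirror-invariant feature-space distance
    between paths, nearest-neighbour uniqueness scores over a pooled corpus,
    metric multidimensional scaling with convex-hull exploration areas,
    session-level summaries and the statistical analyses of the
    fluency-uniqueness trade-off (correlations, overlapping-correlation z
    tests, paired comparisons and a trial-level mixed model), together with a
    synthetic-cohort generator that emulates healthy, Parkinsonian ON/OFF and
    drug/placebo crossover designs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    lme4,
    lmerTest,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
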