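Package: ratemapr
Title: Place-Cell Rate Maps, Place-Field Metrics and Stability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidyverse-native pipeline for hippocampal place-cell analysis
    in open-field recordings: trajectory preprocessing with speed filtering,
    occupancy-normalized and smoothed firing-rate maps, place-field detection
    by thresholded connected components, Skaggs spatial information per
    spike, in-field/out-field specificity ratios, within- and between-session
    rate-map stability correlations, and the group-level statistics
    (Mann-Whitney U, two-way Type-II ANOVA with Bonferroni contrasts).
    Includes a synthetic open-field session generator (mean-reverting
    velocity trajectories, inhomogeneous-Poisson place-cell spike trains,
    genotype-style tuning profiles) so every stage of the pipeline is
    testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    car,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
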