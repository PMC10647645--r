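Package: dynfc
Title: Static and Dynamic Graph-Theoretic Analysis of EEG Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for comparing static and dynamic graph-theoretic
    properties of task-based EEG functional connectivity between groups.
    Parcellated region-of-interest time series are windowed with a sliding
    window, Spearman correlation matrices are computed per window, binarized
    across a threshold sweep, and ten graph measures (segregation,
    integration, centrality, resilience) are extracted per named network.
    Window-resolved metrics are collapsed into a static indicator (mean) and
    a dynamic indicator (coefficient of variation), and groups are compared
    with mixed-effects ANOVA (group x threshold fixed, participant random)
    or a participant-level permutation test, with Benjamini-Hochberg FDR
    control. A latent-state synthetic cohort generator provides calibrated
    test data with configurable group effects on connectivity dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
LinkingTo: Rcpp
Config/testthat/edition: 3
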