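Package: dbnpanel
Title: Dynamic Bayesian Networks for Spatio-Temporal Health-Search Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns two-slice Gaussian dynamic Bayesian networks from weekly
    multi-condition search-frequency panels observed across nested geographic
    units (states and counties). Provides penalized log-likelihood scoring and
    greedy structure search with forward-in-time arcs, bootstrap model
    averaging with data-driven arc-strength significance thresholds, folding
    of the two-slice graph into a cyclic graph with feedback loops,
    ANOVA-style parent variance shares, quartile-stratified generative
    inference, mixed-effects variance decomposition of the spatio-temporal
    structure, missing-data imputation with an injection benchmark, a
    misspecification audit against static Bayesian networks, and a synthetic
    panel generator with known ground-truth structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
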