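Package: hippnet
Title: Longitudinal Hippocampal Subfield Structural Covariance Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for network-based analysis of longitudinal hippocampal
    subfield atrophy. Computes percentage volume-change scores across the 38
    FreeSurfer hippocampal subfields (19 per hemisphere), paired
    baseline/follow-up tests and the left/right asymmetry contrast,
    covariate-adjusted partial Pearson correlations between subfield atrophy
    and cognitive decline, a significance-thresholded structural covariance
    network over subfield volume changes, and four graph-centrality metrics
    (degree, betweenness, closeness, eigenvector) with consensus hub ranking.
    Includes a seeded synthetic cohort simulator with latent-factor co-atrophy
    structure so the full pipeline is testable without access-restricted
    participant data.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
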