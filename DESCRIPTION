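Package: cohortpbn
Title: Cohort-Specific Probabilistic Boolean Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies disease cohorts by simulating probabilistic Boolean
    models of molecular pathways parameterized with cohort-level expression
    statistics. Derives per-miRNA effect sizes (Cohen's d) from two-group
    count data, converts them to common-language effect-size probabilities,
    assigns those probabilities to the initial states of miRNA targets in
    Boolean pathway models, simulates stochastic asynchronous trajectories
    (with optional permanent knockout/overexpression perturbations encoding
    comorbidity), and compares endpoint trajectories across cohorts by staged
    dynamic time warping. Includes Boolean model parsing (BoolNet-style rule
    files, a Boolean SBML-qual subset, SIF export), an exact small-network
    jump-chain oracle, attractor enumeration, change-point detection, and a
    seeded synthetic-data generator so the whole pipeline runs without
    external data.
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
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
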