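Package: riverspom
Title: Metapopulation Dynamics on Expanding and Contracting Stream Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled eco-hydrological simulation of aquatic metapopulations on
    intermittent (temporary) stream networks. Daily catchment discharge is
    generated from a Poisson rainfall / linear-reservoir stochastic model with
    a Gamma stationary distribution; discharge drives hierarchical expansion
    and contraction of a dendritic stream network through persistency-ranked
    activation thresholds; and a dynamic stochastic patch occupancy model
    (SPOM) simulates colonization and extinction of a focal species on the
    pulsing network. Includes synthetic dendritic network generation,
    connectivity (largest connected portion) statistics and duration curves,
    static-equivalent network comparisons, Monte-Carlo scenario ensembles over
    climate and persistency configurations, survival sensitivity maps over
    colonization/extinction trait grids, and an exact Markov-chain oracle for
    small networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
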