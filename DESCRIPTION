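Package: fleetsim
Title: Spatial Agent-Based Simulation of Information Sharing in Fishing Fleets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A spatially explicit agent-based model of a fishing fleet
    harvesting mobile fish schools on a periodic two-dimensional domain.
    Fishing agents search intermittently (ballistic motion with random
    reorientation), sense schools locally, and may share school locations
    over a reciprocal social network with tie weight lambda. Seasons are
    closed by a total allowable catch (TAC) or by individual quotas (IFQ),
    optionally with progressive stock depletion. The package provides the
    season engine, Monte-Carlo search-time characterization and turn-rate
    optimization, catch-rate time series and normalized objective functions
    for fleet catch rate, equity between agents and temporal stability of
    landings, percentile-group (successful/unsuccessful agent) analyses,
    and a seeded sweep driver over sharing level, species mobility,
    depletion and management regime, with tidy outputs and ggplot2 figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
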