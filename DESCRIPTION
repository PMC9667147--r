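Package: streamdyn
Title: Stochastic Simulation of Temporary Stream Network Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the expansion and retraction of the active portion of
    temporary (non-perennial) stream networks. Daily streamflow is generated by
    a marked-Poisson / linear-reservoir model whose flow duration curve defines
    a time-varying persistency threshold; under hierarchical structuring, nodes
    of the geomorphic network switch between wet and dry states whenever their
    local persistency crosses that threshold. Provides synthetic river-network
    generation, climate-driven persistency fields with three spatial allocation
    schemes (random, topographic wetness index, contributing area), active
    length and largest-connected-patch time series, analytic and empirical
    flow and stream-length duration curves, and six preset hydroclimatic
    scenarios.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
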