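Package: tcloop
Title: Bistable Dynamics of a Thalamocortical Pain-Processing Loop
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses a three-population firing-rate model of the
    thalamocortical loop formed by the ventroposterolateral thalamic nucleus (VPL),
    the primary somatosensory cortex (SC) and the thalamic reticular nucleus (TRN),
    in which GABAergic efficacy acts as a bifurcation parameter. Provides Hill-type
    interaction kinetics, the coupled ODE system and its analytic Jacobian, adaptive
    trajectory integration, exhaustive equilibrium location via a scalar steady-state
    reduction with stability classification, saddle-node threshold detection by
    bisection on equilibrium count, basin-of-attraction mapping on grids of initial
    conditions, and model variants (reversed excitatory GABA, fixed gain or fixed
    shift). Results are returned as tibbles with ggplot2 autoplot methods and
    broom-style tidiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
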