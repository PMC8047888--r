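Package: removalOpt
Title: Spatial State-Space Population Modelling and Optimal Allocation of
    Removal Effort
Version: 1.0.0
Authors@R: person("removalOpt", "Developers",
    email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits a spatially explicit Bayesian Gompertz state-space model to
    invasive-species removal records (trap captures and trap-day effort) on a
    river network, with a proper conditional-autoregressive (CAR) spatial
    field, covariate effects and Poisson catch-per-unit-effort observation.
    From the posterior it computes per-unit equilibrium densities and
    optimizes the spatial allocation of a fixed total capture effort to
    minimize whole-area equilibrium density, by simulated annealing on a
    softmax reparameterization, a greedy increment algorithm and an exact
    KKT water-filling solver, and forward-simulates trajectories to estimate
    the time to reach a management target density. Includes a synthetic-data
    generator reproducing the assumed statistical structure of removal
    programs for validation without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    rjags,
    coda,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: JAGS (>= 4.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
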