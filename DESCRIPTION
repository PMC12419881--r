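Package: meanflame
Title: Master Equations with Mean-Field Limits for Stochastic Population Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and integrates hybrid stochastic population models that
    track explicit master-equation states near absorbing states (extinction,
    disease-free states) and collapse the remaining state space into
    mean-field limits, coupled through a truncated-Poisson boundary term.
    Includes a generic equation-system builder, exact master-equation and
    Gillespie simulation oracles, and ready-made models for birth-death
    processes, Lotka-Volterra predator-prey dynamics, spatial SIRS
    metapopulations and a staged tree-dispersal model on a climate-driven
    landscape.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    Matrix,
    stats,
    utils,
    methods,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
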