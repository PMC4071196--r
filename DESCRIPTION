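Package: fluxgp
Title: Dynamic Metabolic Flux Estimation with Dependent Gaussian Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-output Gaussian processes constructed by convolving shared
    white-noise sources with Gaussian smoothing kernels, extended with their
    derivative processes. Because a convolution-constructed Gaussian process
    and its time derivative are jointly Gaussian, the joint posterior over
    metabolite concentrations and their derivatives can be pushed through a
    stoichiometric linear system to give non-parametric, time-resolved
    estimates of metabolic fluxes with exact Gaussian uncertainty propagation.
    Includes closed-form covariance calculus for the convolution construction,
    maximum a posteriori hyperparameter estimation by multistart Nelder-Mead,
    posterior prediction for functions and derivatives, flux estimability
    analysis for underdetermined stoichiometries, and ODE-based synthetic
    time-course generators (oscillating signals, a linear pathway with
    feedback regulation, a branched pathway, and a three-metabolite nitrogen
    assimilation surrogate) with ground-truth derivatives and fluxes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
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
    yaml
Suggests:
    mvtnorm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
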