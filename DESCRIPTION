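Package: spinetrait
Title: Phylogenetic Comparative Analysis of Neural-Spine Metaplasia and Body Size in Theropods
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Bayesian phylogenetic comparative toolkit built around a
    "phylogenetic t-test": generalized least squares regression of a
    continuous trait (ln femur length, a body-size proxy) on a binary
    character (presence of metaplastic neural-spine projections) under a
    Brownian-motion covariance with Pagel's lambda, delta and kappa tree
    scalings. Provides maximum-likelihood and Metropolis-Hastings MCMC
    fitting, harmonic-mean marginal likelihoods with 2-delta log Bayes
    factors for model choice, reversible-jump MCMC ancestral-state
    reconstruction of binary characters under an Mk model with an
    exponential rate hyperprior, Brownian-motion ancestral estimates for
    continuous traits, simulators for Yule trees and traits, and a packaged
    comparative dataset of femur length and neural-spine projection codes
    for 56 theropod species.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp,
    RcppArmadillo
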