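Package: circvelo
Title: Manifold-Constrained RNA Velocity on Periodic and Interval Manifolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generative modelling of spliced and unspliced single-cell UMI
    counts on a one-dimensional latent manifold, with the cell cycle (a
    circular coordinate) as the primary application. Implements two-stage
    Bayesian inference by stochastic variational inference: manifold learning
    estimates a circular phase per cell and Fourier harmonics per gene from
    spliced counts; velocity learning estimates splicing and degradation
    rates and an angular-speed function from unspliced counts, with
    mean-field or low-rank multivariate normal variational families and a
    Hamiltonian Monte Carlo backend. Includes a structured count simulator
    with correlated kinetic parameters, posterior utilities (cell cycle
    period, unspliced-spliced delays, credible-interval comparisons), an
    approximate SVD point estimator of the period, and a proof-of-principle
    B-spline extension to nonperiodic pseudotime intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    MASS,
    optparse,
    Seurat,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
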