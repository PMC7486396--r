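Package: zipfdyn
Title: Demographic Dynamics of City-Size Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how city-size distributions emerge from
    demographic dynamics. Populations evolve under environment (projection)
    matrices built from vital rates and intercity migration probabilities;
    migration flows are decomposed into symmetric (gravity-like) and
    antisymmetric parts. Deterministic environments yield a stationary
    structure set by the leading eigenvector, with convergence governed by
    the spectral gap. When vital and migration rates fluctuate with
    vanishing temporal means, the population-share dynamics becomes driftless
    multiplicative growth and the time-averaged rank-size distribution
    approaches Zipf's law; the package simulates this regime with the
    ghost-city lower-boundary rule, solves the associated Fokker-Planck
    equation (stationary power laws, lognormal transient, eigenfunction
    expansion) analytically and numerically, and provides rank-size and
    information-theoretic diagnostics (Kullback-Leibler divergence to the
    Zipf reference, surprise, fitness/neutrality reports).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
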