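Package: vacdiag
Title: Spectral Estimation for Reversible Dynamics with Error Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates eigenvalues and eigenfunctions of the Markov
    transition operator of a reversible process from trajectory data via
    the variational approach to conformational dynamics (VAC), the method
    underlying Markov state models and time-lagged independent component
    analysis.  Provides reversible-diffusion simulators, a grid-discretized
    generator oracle with exact spectra and correlation matrices, subspace
    distances in L2(mu), Rayleigh-Ritz and sharp long-lag approximation
    bounds, the VAC condition number, and a data-driven plug-in estimate of
    the asymptotic mean squared estimation error, together with scripted
    reproductions of benchmark experiments on Ornstein-Uhlenbeck and
    two-dimensional double-well diffusions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
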