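Package: gridcode
Title: Multiscale Grid-Cell Population Codes for Dynamic Trajectories
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Theory, simulation and decoding of modular (grid-cell-like)
    population codes for dynamic two-dimensional trajectories. Allocates
    neurons and grid spacings across modules to optimize readout resolution
    for a given motion statistic (simple random walk or power-law mean square
    displacement), simulates inhomogeneous Poisson spike trains from periodic
    Gaussian receptive fields, and reads out position with an optimal
    recursive Bayesian filter or a near-optimal kernel (filtered spike count)
    decoder. Includes trajectory generators (random walk and fractional
    Brownian motion with exact circulant-embedding covariance), mean square
    displacement estimation with power-law fitting, and experiment runners
    with confidence-interval error reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
VignetteBuilder: knitr
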