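Package: effcoding
Title: Optimal Nonlinearities for Noisy Neural Encoders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying efficient coding in one- and two-pathway
    neural circuits with noise entering upstream of a saturating
    nonlinearity, at the stochastic (scaled-Poisson) response stage, and
    downstream of it.  Solves exactly for the input-output nonlinearities
    that minimise the mean squared error of an optimal linear stimulus
    decoder (a variational/KKT fixed-point problem), solves the coupled
    integral equations for pairs of pathways by Picard iteration, and
    maps how optimal strategies (slope, offset, overlap, ON-OFF versus
    ON-ON polarity) depend on the location, magnitude, and correlation
    of the noise.  Includes Monte Carlo simulation of the encoding model,
    Gaussian-expectation quadrature, signal-to-noise ratio and mutual
    information estimation (binless nearest-neighbour and binned
    differential entropy), and logistic-nonlinearity parameter sweeps.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    pracma,
    jsonlite,
    yaml,
    RANN
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
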