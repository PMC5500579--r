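Package: otcalib
Title: Optical Trap Calibration by Kramers-Moyal Reconstruction and
    Power-Spectrum Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Nonlinear, data-driven calibration of optical tweezers from
    bead-position time series. Estimates the drift function and the
    position-dependent diffusion coefficient of a trapped bead directly
    from the recorded series via binned Kramers-Moyal conditional moments
    with zero-lag extrapolation, tests the Markov property of the series
    (Markov-Einstein time scale) with a three-point chi-squared test, and
    compares the result against the classical Lorentzian power-spectrum
    calibration (corner frequency, trap stiffness, volt-to-metre
    conversion factor). Includes an Euler-Maruyama Langevin simulator for
    multiplicative-noise traps used for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
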