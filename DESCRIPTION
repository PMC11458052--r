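Package: oritune
Title: Orientation Tuning of Face-Identity Recognition Under Inversion and
    Contrast Negation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how picture-plane inversion and contrast
    negation reshape the orientation tuning of familiar-face identity
    recognition. Provides wrapped-Gaussian orientation filtering of face
    images in the Fourier domain with luminance and RMS-contrast
    equalization, a procedural synthetic-face generator, construction of
    blocked same/different trial schedules, simulation of signal-detection
    observers with known Gaussian orientation tuning, trial scoring with
    log-linear corrected d-prime, and Bayesian hierarchical Gaussian
    tuning-curve models (fit with JAGS) including credible-interval
    comparisons, posterior predictive curves, and subject-level parameter
    correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    coda,
    rjags,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
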