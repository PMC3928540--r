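Package: classim
Title: Classification-Image Analysis of Detection-in-Noise Experiments
Version: 0.1.0
Authors@R: person("J.", "Doe", email = "jdoe@example.com", role = c("aut", "cre"))
Description: Tools for simulating and analysing yes/no detection experiments
    in truncated Gaussian pixel noise, built around the Ebbinghaus-Titchener
    size-contrast figure. Renders parametric dot-and-inducer stimuli as
    contrast images, runs adaptive 2-down/1-up staircases with ideal,
    CSF-limited ideal, and linear-template observers, fits Weibull
    psychometric functions to obtain contrast-energy thresholds and
    efficiencies, and estimates classification images by reverse correlation
    with radial and spectral profiles, bootstrap and randomization error
    bands, and single- and two-sample Hotelling T-squared tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
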