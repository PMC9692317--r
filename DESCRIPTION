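Package: spicpms
Title: Background Signal Correction and Particle Sizing for Single-Particle ICP-MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for millisecond single-particle inductively coupled plasma
    mass spectrometry (SP-ICP-MS). Separates nanoparticle pulse signals from a
    continuous dissolved-element background by histogram subtraction with
    particle-count rescaling, converts net pulse intensities to equivalent
    spherical diameters through a transport-efficiency calibration, and
    provides a Poisson trace simulator with known ground truth for validating
    the correction. Includes classical n-sigma and Poisson decision thresholds
    for comparison, tidy accessors for all result objects, ggplot2 figures,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
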