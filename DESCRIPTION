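Package: spumaphen
Title: Temperature-Driven Phenology Model for the Meadow Spittlebug
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and estimates the preimaginal phenology of the meadow
    spittlebug (Philaenus spumarius), the principal European vector of
    Xylella fastidiosa. The model couples Briere temperature-development
    rate functions for the post-diapausing egg and the five nymphal
    instars, a degree-day rule for egg diapause termination, a Beta
    distribution of initial egg physiological age, and an age-structured
    advection (Kolmogorov) solver that transports cohort density through
    the stages under an arbitrary temperature forcing. Includes
    parameterization from constant-temperature chamber cohorts, two-step
    field calibration (rate refinement, then an exhaustive grid search for
    the diapause thresholds), synthetic weather/chamber/survey generators,
    and goodness-of-fit evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
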