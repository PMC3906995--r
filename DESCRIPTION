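Package: fociPulse
Title: Single-Cell Quantification of DNA Double-Strand Breaks and p53 Pulse Dynamics
Version: 0.1.0
Authors@R:
    person("Avery", "Quinn", email = "avery.quinn@example.org", role = c("aut", "cre"))
Description: Tools for quantifying DNA double-strand breaks (53BP1 foci) and
    pulsatile p53 dynamics in single living cells. Provides a seeded synthetic
    time-lapse generator (per-cell break counts, exponential repair, excitable
    p53 pulses, rendered fluorescence image stacks), automated foci enumeration
    by top-hat filtering, Canny edge detection and marker-directed watershed,
    per-cell exponential repair-kinetics fitting, p53 pulse calling in reporter
    trajectories, and the dose-response statistics linking break number to pulse
    probability (binned fractions, robust linear regression with confidence
    bands, rank-sum and Kolmogorov-Smirnov tests, repeated-damage conditional
    response, and DNA-content based cell-cycle classification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    png
Config/testthat/edition: 3
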