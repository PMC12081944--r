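Package: oddballerp
Title: Simulation and Analysis of Auditory Spatial Oddball ERP Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for validating auditory spatial change-detection (oddball)
    paradigms with event-related potentials (ERPs). Generates constrained
    oddball stimulus sequences, synthesizes multi-channel EEG cohorts with
    parameterized P1/N1/P2 components and deviance-related MMN and P3b
    responses over 1/f background noise, and analyses them with a windowed-sinc
    FIR preprocessing chain, P1-anchored onset-latency alignment,
    fractional-area-latency and windowed mean-amplitude component measures,
    jackknife-corrected mixed repeated-measures ANOVA with
    Benjamini-Hochberg-adjusted post hoc tests, JZS default-prior Bayes
    factors, and logit-transformed behavioral accuracy analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
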