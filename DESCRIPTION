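Package: pupilwave
Title: Pupillometry Preprocessing and Run-Length Calibrated Waveform Comparison
Version: 0.1.0
Authors@R:
    person("pupilwave", "developers", role = c("aut", "cre"),
           email = "maintainer@pupilwave.invalid")
Description: Tools for dyadic pupillometry studies: preprocessing of raw 60 Hz
    binocular eye-tracker exports into baseline-corrected pupil-diameter-change
    (dPD) timecourses (eye-to-eye regression imputation, averaging, 10 Hz
    downsampling, missingness-based exclusion, rolling-median despiking, blink
    interpolation, early-window baseline subtraction); between-group comparison
    of dPD waveforms by consecutive pointwise one-tailed Welch t-tests with
    family-wise error controlled by a Monte Carlo AR(1) run-length threshold;
    supporting one-way and two-way (Type II) ANOVAs with Holm post hoc tests;
    and a synthetic dyad-recording generator so the whole analysis is testable
    without access to human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
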