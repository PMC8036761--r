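Package: thermopulse
Title: Pulsed Transient-Plane-Source Simulation and Analysis for Label-Free Cell Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward electro-thermal simulation and slope-based analysis for a
    pulsed, DC transient-plane-source (TPS-derived) biosensor that monitors cell
    sedimentation and proliferation in real time. A planar foil heater under a
    liquid culture is excited with constant-current Joule heating pulses; the
    voltage transient, regressed against the square root of time over a fixed
    early window, yields a slope whose percent change relative to the first
    pulse tracks the insulating cell layer forming at the sensor interface.
    The package provides a one-dimensional implicit finite-difference solver
    for the layered heater/substrate/cell/medium stack, an electrical model of
    the resistive structure (resistance thermometry), synthetic sedimentation
    and yeast growth scenarios rendered into raw pulse datasets, the full
    read-out pipeline (voltage-to-temperature conversion, sqrt-time regression,
    percent-change series, endpoint statistics), and biological quantification
    (endpoint-versus-concentration calibration with inverse prediction, and
    logistic growth fitting with doubling-time estimation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    data.table,
    minpack.lm,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
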