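Package: pendmode
Title: Nonlinear Normal Modes and Resonant Excitation of a Compliant Double Pendulum
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for rhythmic excitation of a
    horizontally swinging, elastically jointed double pendulum driven through
    a commanded motor link. Computes the system's nonlinear normal modes
    (energy-parametrized families of brake orbits) by shooting and numerical
    continuation, implements literature-derived baseline excitation
    controllers (resonant sine, slow position sine, bang-bang with deadzone),
    scores an alternating target-hitting task, and quantifies excited motions
    with an oscillation-frequency estimate, a dynamic-time-warping mode
    metric against the ideal brake orbit, deflection ratio, and phase lag.
    A synthetic-participant generator produces closed-loop joystick-like
    behavior so the full cohort-level statistical comparison can be run
    without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
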