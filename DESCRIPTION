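Package: exohitl
Title: Human-in-the-Loop Optimization of Knee Exoskeleton Assistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Desk-scale simulation of a human-in-the-loop (HITL) controller for
    an active knee exoskeleton. A metabolic-cost estimator (exponential-kernel
    Gaussian process regression on mean-absolute-deviation features from
    four-site wearable accelerometry plus body mass index) feeds a
    covariance-matrix-adaptation evolution strategy (CMA-ES) that searches the
    flexion/extension torque-peak plane; candidate peaks shape a 13-knot
    natural-cubic-spline torque profile tracked by a PID loop against a
    first-order actuator plant. A configurable synthetic walker with known
    metabolic and interaction-torque response surfaces closes the loop so that
    optimizer convergence and estimator accuracy can be studied end to end
    without human recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
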