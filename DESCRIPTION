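Package: impactemu
Title: Low-Rank Representation and Stochastic Emulation of Head Impact
    Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models six-degree-of-freedom head-impact kinematics (triaxial
    linear acceleration and angular velocity sampled at 1 kHz for 100 ms)
    with a low-rank singular value decomposition, and emulates new impacts
    by sampling per-mode scores. Includes the competing biphasic
    (triangle/half-sine) pulse parameterization, kinematic brain-injury
    metrics (HIC15, RIC36, BrIC) and a lumped-parameter brain-skull angle
    metric (BAM), percent-error and Friedman-test evaluation against
    ground truth, power-spectral-density analysis of temporal modes, and a
    calibrated synthetic impact generator so every component is testable
    without access to on-field sensor data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
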