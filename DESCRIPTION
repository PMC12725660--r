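Package: stGclamp
Title: Kinetic Modelling of Blood Glucose Regulation with a Transient
    Glucose Store under Hyperglycemic Clamp Protocols
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates and fits a four-state kinetic model of blood glucose
    regulation in which an insulin-independent transient glucose store (stG)
    carries glucose effectiveness alongside insulin-dependent uptake.
    Provides closed-loop hyperglycemic-clamp and IVGTT simulation, per-mouse
    parameter estimation by meta-evolutionary programming followed by
    bounded nonlinear least squares, decomposition of glucose disposal into
    insulin-independent and insulin-dependent fluxes over time, a synthetic
    mouse-cohort generator emulating chow- and high-fat-diet groups, and the
    group statistics used to track parameter changes with obesity (Welch's t
    with Benjamini-Hochberg adjustment, Williams-type step-down trend tests
    with a Monte-Carlo null, Spearman rank correlation, and IQR outlier
    screening).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    readxl
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
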