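Package: scrlti
Title: Linear Time-Invariant Modelling of Sudomotor Nerve Activity and
    Skin Conductance Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward and inverse modelling of the mapping from sudomotor
    nerve (SN) bursts to skin conductance responses (SCR) under linear
    time-invariant (LTI) assumptions. Provides the Gaussian burst model of
    event-evoked SN activity, a skin conductance response function defined
    by a third-order linear ordinary differential equation, convolution and
    ODE-based prediction, least-squares parameter and gain estimation,
    variance partitioning across canonical, subject-level and epoch-level
    response functions, the full preprocessing chain for nerve and skin
    conductance recordings, and a synthetic-data generator that emulates
    intraneural recording and intraneural stimulation experiments,
    including a gain-depletion nonlinearity at high stimulation rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rlang,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
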