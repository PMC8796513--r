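Package: csftransport
Title: Reduced-Order Simulation of Intrathecal Tracer Transport in the
    Cerebrospinal Fluid System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale in silico trials of intrathecal drug delivery.
    Implements a one-dimensional finite-volume solver for tracer transport
    along the cranio-spinal axis under cycle-averaged (steady-streaming)
    advection and oscillation-induced effective dispersion, with a
    compartmental ventricular system, cardiac and deep-respiration CSF flow
    waveform synthesis, and presets for eight injection/physiology
    scenarios (lumbar puncture, cisterna magna, intracerebroventricular
    routes and protocol variants). Provides spatial-temporal
    pharmacokinetic quantification (AUC, Cmax, Tmax by axial location and
    region), Bland-Altman and linear-regression method-agreement
    statistics, delimited-text matrix input/output in a fixed
    axial-by-time layout, and closed-form synthetic-data generators with
    known transport parameters for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
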