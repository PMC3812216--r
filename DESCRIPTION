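Package: cardiotilt
Title: Closed-Loop Cardiovascular Simulation of Graded Head-Up Tilt
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lumped-parameter (0-D) closed-loop model of the human circulation
    for simulating graded head-up tilt. Includes a four-chamber heart with
    septal and pericardial ventricular interaction and inertial valves, a
    six-branch systemic plus pulmonary circulation with per-compartment
    hydrostatic columns and a nonlinear lower-body venous capacity law,
    arterial and cardiopulmonary baroreflexes with four effector arms, and
    lower-body myogenic autoregulation. Provides beat-by-beat summaries,
    steady-state tilt-response tables, heart-failure and single-factor
    scenario presets, hypothesis toggles (cardiopulmonary reflex, myogenic
    autoregulation, frozen pericardium), and weighted constrained
    least-squares parameter estimation with sensitivity screening and
    covariance-based subset reduction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
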