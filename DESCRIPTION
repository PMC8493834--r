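Package: hergkinetics
Title: Kinetic Modelling and Rapid Characterization of hERG (IKr) Channel Currents
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the rapid delayed-rectifier potassium current
    (IKr) carried by hERG (Kv11.1) channels. Implements a Hodgkin-Huxley
    factorizable six-state Markov gating model with twelve voltage-dependent
    rate parameters, simulation of voltage-clamp protocols (activation,
    deactivation, inactivation, staircase calibration, premature-stimulation
    and action-potential trains), generation of synthetic three-sweep
    patch-clamp recordings (control / activator / full-block) with leak and
    Gaussian noise, joint maximum-likelihood inference of shared channel
    kinetics with cell-specific conductances and voltage offsets, and the
    standard electrophysiological biomarker analyses (bi-exponential
    deactivation fits, Boltzmann conductance-voltage fits,
    rectification-method inactivation, protective-current and
    action-potential-clamp metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo: Rcpp
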