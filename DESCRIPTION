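Package: dbiwin
Title: Adaptive Time-Window Selection for Dynamical Bayesian Inference of
    Coupled Oscillators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequential dynamical Bayesian inference of time-varying phase
    dynamics of two coupled, noisy oscillators, with data-driven selection of
    the analysis time window and of the covariance propagation parameter.
    Includes stochastic simulators of coupled phase and Poincare limit-cycle
    oscillators at cardiorespiratory scales, phase extraction from raw
    oscillatory signals (zero-phase band-pass filtering, analytic-signal
    protophase, protophase-to-phase transformation), quadrature-covariance
    diagnostics, and post-inference coupling-function analysis (coupling
    strength, similarity index, coupling surfaces).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
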