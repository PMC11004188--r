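Package: brownmotor
Title: Brownian Signatures of Human Motor Control: Closed-Loop Simulation
    and Stochastic Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates single-degree-of-freedom closed-loop neuromechanical
    models of human motor behavior (crank turning, static hand posture, quiet
    standing) under noisy forward-path velocity commands, including rival
    control architectures (leaky-integrator disturbance shaping, free-integrator
    loops, and velocity-reference loops with threshold-triggered intermittent
    Gaussian corrective pulses), and provides the stochastic-signature analysis
    that discriminates among them: across-trial ensemble variance with linear
    growth and breakpoint fits, trial-averaged single-window Welch power
    spectral densities, and log-log slope regression in dB/decade with 95%
    confidence intervals. Also generates reference stochastic processes
    (Wiener, Ornstein-Uhlenbeck, n-fold integrated noise, bounded walks) with
    known closed forms for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
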