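Package: grnest
Title: Robust H-Infinity State Estimation for Discrete-Time Stochastic
    Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and observer synthesis for discrete-time stochastic
    gene regulatory networks with leakage, discrete time-varying and
    distributed delays, norm-bounded parameter uncertainty, and
    Bernoulli-dropout measurements. Provides the delayed stochastic
    difference-equation simulator for mRNA/protein concentrations with
    Hill-type regulation, assembly of the Lyapunov-Krasovskii block linear
    matrix inequalities certifying mean-square exponential stability and
    H-infinity disturbance attenuation of the estimation error dynamics, a
    spectral feasibility solver with estimator gain recovery, and
    Monte-Carlo verification of the decay rate and energy-gain definitions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
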