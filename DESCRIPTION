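Package: bayesmech
Title: Bayesian Mechanics of Active Inference in a Cortical Column
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic simulator for the Hamiltonian ("Bayesian
    mechanics") formulation of free-energy-minimising active inference in a
    single cortical column. Provides the Laplace-encoded variational free
    energy and its Legendre-transformed Hamiltonian over a complex
    four-component phase space (perceptual state, motor state and their
    conjugate momenta, i.e. mass-weighted prediction errors), exact
    matrix-exponential propagation and attractor/eigen analysis of the linear
    generative model, a generic fixed-step Runge-Kutta integrator for
    nonlinear models, sigmoid and user-defined stimulus schedules, and a
    stochastic-thermodynamics layer with over-damped Langevin path ensembles,
    Jarzynski and integral entropy fluctuation-theorem estimators,
    Ornstein-Uhlenbeck coloured-noise diagnostics and Fokker-Planck
    steady-state flux fields.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
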