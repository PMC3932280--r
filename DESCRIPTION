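Package: ppdiffusion
Title: Diffusive Predator-Prey Dynamics with General Functional Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and dynamical-analysis toolkit for a one-dimensional
    reaction-diffusion predator-prey model with a general nonlinear functional
    response (Holling type II, simplified Holling type IV, or user supplied)
    and a predator death rate that saturates with predator density. Provides
    equilibrium location and classification for the reduced ODE system,
    a method-of-lines no-flux (Neumann) PDE simulator, dissipativity and
    permanence/extinction diagnostics, mode-wise linearized stability and
    Turing-instability scans, a Lyapunov-energy global-stability diagnostic,
    and an a-priori certificate excluding nonconstant positive steady states
    at large diffusion.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
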