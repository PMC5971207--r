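Package: ssnvar
Title: Stochastic Stabilized Supralinear Networks and the Analysis of Neural Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of stimulus modulation of neural
    variability in recurrent rate networks. Implements the stochastic
    stabilized supralinear network (SSN) with multivariate
    Ornstein-Uhlenbeck input noise, in reduced two-population, ring, and
    stochastically spiking forms, together with two competitor dynamical
    regimes (a marginally stable multi-attractor ring and a chaotic random
    rate network). Provides fixed-point and linearized (Lyapunov-equation)
    covariance analysis, doubly stochastic Poisson spike-count generation,
    Fano factors and noise correlations by tuning similarity, factor
    analysis of normalized spike counts, Welch spectra and Vm-LFP
    coherence, circular-Gaussian bump-kinetics decomposition of population
    covariance, and extraction of variability suppression and recovery
    timescales.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
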