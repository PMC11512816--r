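Package: aatask
Title: Simulation and Analysis of Approach-Avoidance Decisions Under
    Outcome Predictability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying approach-avoidance decisions when the
    action-outcome contingency is predictable versus stochastic, as in
    elevator-style virtual-reality threat tasks.  Provides a synthetic
    cohort generator (trial schedules, drift-diffusion choices and
    response times, event-locked electrocardiogram and electromyogram
    traces, subjective evaluations), trial-level behavioural analyses
    with hierarchical Bayesian logistic models, Wiener first-passage-time
    likelihoods and model comparison for drift-diffusion models, finite
    mixture modelling of choice behaviour for latent-class discovery,
    ECG/EMG preprocessing (R-peak detection, inter-beat-interval artifact
    correction, burst detection), and time-resolved GLM inference on
    physiological epochs with cluster-mass permutation testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    rjags,
    coda,
    car,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
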