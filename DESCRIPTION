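Package: satdm
Title: Sequential-Sampling Decision Models and Speed-Accuracy Tradeoffs
    Under Time Pressure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying perceptual decision making under time
    pressure.  Generates synthetic sessions for deadline and
    decaying-reward choice tasks (sequentially revealed dot stimuli, hard
    deadlines, linearly decaying gains and losses, time-dependent
    gambles); fits Weibull speed-accuracy tradeoff (SAT) functions by
    maximum likelihood; computes expected-gain curves and optimal mean
    response times for decaying-reward schedules and inverts the model to
    design reward decay rates; simulates seven sequential-sampling
    decision models (basic drift diffusion, trial-variant drift,
    collapsing boundary, leaky integration, urgency gating, leak plus
    urgency, and a tri-stable attractor) at the single-trial level;
    predicts first-passage behaviour with a one-dimensional Fokker-Planck
    solver, fits models to binned choice and response-time summaries by a
    Gaussian summary likelihood, and compares them by AIC; and provides
    the accompanying behavioral analyses (deadline-proximity performance,
    response-time matching, psychophysical evidence kernels, and
    sequential effects).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
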