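Package: revlearn
Title: Reversal Learning Simulation, Bayesian Change-Point Inference, and
    Pupillometry Statistics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying expected and unexpected uncertainty in
    probabilistic reversal learning. Simulates binary-choice reversal-learning
    sessions under response-contingent or stochastic reversal rules; estimates
    per-trial state change probability and state entropy with a beta-Bernoulli
    hidden Markov model solved by sequential Monte Carlo (particle filtering),
    with an exact enumeration oracle; fits softmax choice models (Bayesian HMM,
    Rescorla-Wagner, no-reversal) by multistart maximum likelihood with AIC/BIC
    model comparison and model-recovery utilities; generates synthetic two-eye
    pupil recordings with known effect structure; preprocesses pupil traces
    (blink removal, outlier padding, 50 Hz resampling, Savitzky-Golay smoothing,
    feedback-locked baseline-corrected epochs); and runs mass-univariate
    per-time-bin linear mixed models with likelihood-ratio tests and
    cluster-based permutation correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    withr
Config/testthat/edition: 3
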