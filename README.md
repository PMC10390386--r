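# revlearn

Simulation and analysis toolkit for probabilistic reversal-learning studies
that separate **expected uncertainty** (the noise level of a stimulus-reward
contingency: the better option pays off with probability 0.65, 0.75 or 0.85)
from **unexpected uncertainty** (the possibility that the contingency has
just reversed). It is aimed at computational cognitive neuroscientists who
want a fully testable, synthetic-data version of the complete pipeline:
behavior, Bayesian trial-by-trial inference, model comparison, and
feedback-locked pupillometry statistics.

## What is inside

* **Task simulation** — two-alternative guessing sessions under
  response-contingent (8 consecutive preferred choices) or stochastic
  (0.06/trial) reversal rules, driven by pluggable agents (Bayesian HMM,
  Rescorla-Wagner, no-reversal, scripted), with behavioral summaries and
  reversal-aligned curves.
* **Bayesian observer** — a hidden Markov model over the preferred side
  with a Beta prior on the reversal rate and a [0.5, 1]-truncated Beta
  prior on the contingency strength, solved by a C++ particle filter whose
  per-trial outputs are the posterior over sides, the one-step predictive,
  the *state change probability*
  `q_t = P(z_t != y_t | x_1..t)`, and the *state entropy* `H(q_t)` in bits
  (`H` is 1 at `q = 0.5`, 0 at `q = 0` or `1`). An exact `2^t` enumeration
  oracle validates the filter to 0.01 absolute error.
* **Model fitting** — multistart maximum likelihood for the three softmax
  choice models, AIC/BIC, model recovery and generative checks.
* **Pupillometry** — a synthetic 250 Hz two-eye generator with known
  effect structure (feedback valence, `q`, `H(q)` in mm), the full
  preprocessing chain (eye averaging, blink deletion, 3 SD outlier removal
  with 40 ms padding, 50 Hz resampling, gap interpolation, Savitzky-Golay
  smoothing), and feedback-locked baseline-corrected epochs of exactly 350
  bins (-1 s to +6 s).
* **Statistics** — per-bin random-intercept linear mixed models (a
  profiled-ML C++ engine verified against lme4) with likelihood-ratio
  tests, cluster-based permutation correction, the dual-basis analysis
  (`q` and `H(q)` as basis functions), and the below/above-0.5 interaction
  model.

## Worked example

```r
library(revlearn)

cfg <- condition_config("exp2a")          # 100 trials, 0.85/0.15, 0.06 switching
agent <- agent_spec("bayes_hmm", c(alpha_p = 1, beta_p = 1,
                                   alpha_a = 1, beta_a = 12, beta = 8))
session <- generate_session(cfg, agent, seed = 42)
summarize_behavior(session)
#> preferred_pct  rewarded_pct    switch_pct
#>      85.00000      73.00000      23.23232
```

The agent found the preferred side on 85% of trials but was rewarded on
only 73% — the gap is the expected uncertainty of the 0.85/0.15
contingency. Running the filter gives the trial-by-trial uncertainty
estimates:

```r
est <- run_filter(hmm_params(1, 1, 1, 12), session,
                  n_particles = 10000, seed = 1)
head(est[, c("trial", "posterior_z1", "state_change_probability",
             "state_entropy", "predictive_x1")], 4)
#>   trial posterior_z1 state_change_probability state_entropy predictive_x1
#> 1     1       0.7500                   0.2500        0.8113        0.5000
#> 2     2       0.4464                   0.5536        0.9917        0.6410
#> 3     3       0.2724                   0.7276        0.8449        0.4745
#> 4     4       0.5297                   0.5297        0.9975        0.3922
```

Around the session's first reversal (trial 9) the state entropy jumps from
0.532 to 0.996 bits — the model registers that the learned contingency may
no longer be valid. Fitting a competing model to the same choices:

```r
fit_mle(fit_spec("rescorla_wagner", n_starts = 5, seed = 2), session)
#> rescorla_wagner fit: nll = 28.037, AIC = 60.07, BIC = 65.28 (n = 100)
#>  alpha   beta
#> 0.5843 3.6600
```

The pupil arm is driven the same way: `generate_recording()` synthesizes a
250 Hz two-eye stream whose evoked amplitudes encode `q_t` and `H(q_t)`,
`clean_series()` + `epoch_and_baseline()` produce the 350-bin epochs, and
`cluster_permutation()` / `dual_basis_model()` test which uncertainty
signal drives the response with family-wise error control. The whole study
runs from one config via `run_study()` or the `revlearn` CLI
(`inst/cli/revlearn`).

## Layout

```
R/                 task_sim, hmm_filter, model_fit, pupil_synth,
                   pupil_prep, lmm_cluster, pipeline, cli
src/               particle filter and profiled-ML LMM engine (Rcpp)
tests/testthat/    unit, property and acceptance suites
vignettes/         methods vignette (models, assumptions, calibration)
scripts/           acceptance.R
```
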