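---
title: "Models and methods: uncertainty estimation in reversal learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: uncertainty estimation in reversal learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revlearn)
```

# The scientific problem

In a probabilistic reversal-learning task a player repeatedly guesses which
of two response options (left/right) is currently "preferred": the correct
answer coincides with the preferred side only with probability
$p \in \{0.65, 0.75, 0.85\}$ (*expected* uncertainty — irreducible outcome
noise), and the preferred side itself occasionally reverses (*unexpected*
uncertainty — the learned contingency may no longer be valid). The package
implements, end to end and on synthetic data, the computational machinery
needed to study how these two kinds of uncertainty can be separated: task
simulation, Bayesian trial-by-trial inference of reversal probability,
choice-model fitting and comparison, synthetic pupillometry with known
ground truth, preprocessing, and mass-univariate mixed-model statistics.

# Task model

A session is a sequence of trials $t = 1..T$ with hidden preferred side
$z_t \in \{0, 1\}$, observed correct side $x_t$ with
$P(x_t = z_t) = p$, choice $y_t$, and reward $\pm 1$ points. Two reversal
regimes are implemented:

* **response-contingent**: $z$ flips on the trial after the player has
  chosen the preferred side eight times in a row (reward-irrelevant;
  choosing the nonpreferred side resets the count). The switch is applied
  after the feedback of the streak-completing trial, effective from the next
  trial — the exact instant is not fixed by the protocol, and this choice is
  the only causally consistent one (the trigger depends on the current
  trial's choice).
* **stochastic**: $z$ flips independently with probability $h = 0.06$
  between consecutive trials, so a 100-trial session carries
  $99 \times 0.06 = 5.94$ expected reversals.

The three named conditions are `exp1` (150 trials, $p = 0.75$,
response-contingent), `exp2a` (100 trials, $p = 0.85$, stochastic) and
`exp2b` (100 trials, $p = 0.65$, stochastic). Phase timing (fixation
U(1.5, 2) s, response ≤ 2 s, wait U(1.5, 2) s, feedback 3 s) is simulated
only to produce feedback-onset timestamps for the pupil generator; the
simulated response time is drawn U(0.4, 1.5) s, a typical two-alternative
key-press latency, since agents always respond. The session format
nevertheless carries missing choices to mirror real data.

# The Bayesian observer

The inference model is a hidden Markov model over $z_t$ with two marginal
unknowns: the per-transition reversal probability
$a \sim \mathrm{Beta}(\alpha_a, \beta_a)$ and the contingency strength
$p \sim \mathrm{Beta}(\alpha_p, \beta_p)$ truncated to $[0.5, 1]$ (the
truncation is what makes "preferred" mean preferred). Marginalizing $a$ and
$p$ makes the state transitions a beta-binomial predictive in the number of
past reversals $r_t$ and the observation likelihood a beta-Bernoulli
predictive in the number of past matches $m_t$, plus a truncation
correction $c_t$ that is itself computable recursively from
$c_0 = 0.5^{\alpha_p+\beta_p} / \left[ B(\alpha_p, \beta_p) -
B(0.5; \alpha_p, \beta_p)\right]$. A hidden-state *history* is thus fully
summarized by $(z_t, r_t, m_t, c_t)$ — an exact compression, not an
approximation.

Exact posterior computation sums over all $2^t$ histories and is
implemented as `exact_posterior()` (pure R, usable to $t \le 14$); it is
the package's oracle. The production path `run_filter()` is a sequential
Monte Carlo filter (C++): each particle carries the sufficient statistics,
is branched over both current states, conditioned on the observed correct
side, renormalized, and resampled back to the particle budget.

Per trial the filter reports the posterior over sides, the one-step-ahead
predictive $P(x_t | x_{1:t-1})$ (computed *before* conditioning — this is
what the choice model consumes), the **state change probability**
$q_t = P(z_t \neq y_t | x_{1:t})$ (posterior probability that the
preferred side differs from the player's reference choice), and the
**state entropy** $H(q_t)$ in bits. Because binary entropy is symmetric,
$H$ computed from the side posterior and from $q_t$ coincide; a single
implementation (`binary_entropy()`) is shared everywhere, including the
regression basis functions below.

Numerical and design choices:

* Particle count defaults to 10,000 (tests use $10^5$ against the oracle,
  where agreement is within 0.01 absolute posterior error); nothing in the
  emulated design fixes a count.
* Weights are renormalized at every step, which the recursion licenses
  because only probability ratios matter; per-step factors are bounded
  probabilities, so underflow cannot occur and linear-domain weights with
  max-shift normalization are sufficient.
* Resampling is systematic by default (multinomial available), with the
  two state-branches laid out in contiguous blocks. Interleaving the
  branches pairwise would make the weight sequence periodic with the
  sampler's stride and collapse the particle set to one branch — a bug
  caught by the enumeration oracle during development.
* The $\alpha_a \to 0$ limit reduces to the closed-form no-reversal
  recursion **exactly only for symmetric shape priors**
  ($\alpha_p = \beta_p$): the $[0.5,1]$-truncated prior and its mirrored
  complement then tile the full untruncated Beta. The shared limit test
  uses symmetric shapes; for asymmetric shapes the closed form (which
  assumes no truncation) genuinely differs.

# Choice models and fitting

Choices are generated from model values through a softmax with inverse
temperature $\beta$ ($\beta = 0$ random, $\beta \to \infty$ greedy). Three
models are fitted by maximum likelihood over responded trials (missed
trials still advance the model state):

| model | values entering softmax | free parameters |
|---|---|---|
| `hmm` | one-step predictive of the filter | $\alpha_p, \beta_p, \alpha_a, \beta_a, \beta$ |
| `rescorla_wagner` | $Q$ values, delta rule, $Q_1 = (0.5, 0.5)$ | $\alpha, \beta$ |
| `no_reversal` | beta-Bernoulli predictive, hyperbolic learning rate | $\alpha_p + \beta_p, \beta$ |

Reward for the delta rule is coded $R \in \{0, 1\}$ so that $Q$ lives on
the same $[0, 1]$ scale as the probabilities the other models feed to the
same softmax; the symmetric start at 0.5 presumes this coding. Choice
probabilities are floored at $10^{-12}$ inside the log.

Fitting is best-of-$n$ multistart constrained minimization (default 10
starts; shape-type parameters drawn log-uniform in $[10^{-3}, 10^3]$,
$\beta$ in $[0, 10^3]$, learning rate uniform in $[0,1]$). The smooth
two-parameter models use L-BFGS-B; the five-parameter HMM objective is a
particle-filter likelihood, deterministic under a fixed per-fit filter seed
but only piecewise smooth in the parameters (resampling decisions change
discretely), so it is optimized by Nelder-Mead on a log scale — a
derivative-free method in the same constrained-local-optimization family
as SLSQP (no SLSQP implementation ships with the supported R
toolchain). AIC ($2k + 2\,\mathrm{NLL}$) and BIC
($k \ln n + 2\,\mathrm{NLL}$, $n$ = responded trials) accompany every fit;
`model_recovery()` reproduces the generate-fit-compare table with paired
t-tests on per-dataset AIC, and `generative_check()` simulates ten
sessions per fitted parameter vector and summarizes behavior
(preferred/rewarded/switch percentages, reversal-aligned curves).

# Synthetic pupillometry: the stated world

`generate_recording()` produces what the preprocessing and statistics
stages are meant to consume: a 250 Hz two-eye diameter stream. Its
components, with defaults and why:

* **Baseline**: participant-level constant, 4 ± 0.3 mm across participants
  — the adult photopic range.
* **Evoked response**: unit-peak gamma-density kernel, shape 3, scale
  0.5 s (peak exactly 1 s post-feedback, support effectively ≤ 4 s). A
  smooth unimodal kernel peaking around 1 s is the empirical shape of
  feedback-locked dilations; nothing downstream depends on the exact form.
* **Effect structure**: the response amplitude of trial $t$ is
  $b_{fb}\,\mathbf{1}\{\text{negative}\} + b_q\,q_t + b_H\,H(q_t)$ in mm
  (defaults 0.2, 0.3, 0.3 — evoked pupil effects of 0.1–0.3 mm).
* **Noise**: common AR(1) (coefficient 0.99 at 250 Hz, innovation SD
  0.035 mm, i.e. marginal SD ≈ 0.25 mm — the slow arousal fluctuation
  level of real recordings) plus independent 0.03 mm white noise per eye.
  The noise floor matters more than usual here: with an unrealistically
  quiet background the 3 SD outlier rule starts clipping the peaks of
  large evoked responses, and that censoring is a concave distortion that
  loads spuriously onto the entropy regression basis. This was diagnosed
  explicitly (a $t = 9$ entropy coefficient under a purely linear ground
  truth, vanishing in an exactly-linear control with the same predictors)
  and fixed once by setting the background to its realistic level.
* **Blinks**: Poisson events at 0.2/s, 0.1–0.4 s, mostly binocular —
  ~5% missing samples, the interpolation load typical of real
  recordings (means of 5–8%).

What the generator does *not* emulate: gaze-dependent foreshortening,
luminance responses, slow drift (available but off by default so
baseline-correction tests stay exact), and any nonlinear amplitude
saturation. A green detection test therefore establishes that the analysis
recovers linear-in-predictor amplitude structure from realistically noisy,
blink-riddled two-eye data — not that it is robust to optical artifacts.

# Preprocessing chain

`clean_series()` applies, in order: eye averaging; deletion of samples
flagged as blink in *either* eye; deletion of samples deviating more than
3 SD from the series mean, padded by 10 samples (40 ms) each side —
applied before resampling because the padding is specified in 250 Hz
samples; resampling to 50 Hz by missing-aware means of non-overlapping
5-sample blocks (stamped at block-center times); linear interpolation of
remaining gaps (nearest-value extension at the edges, counted as
interpolated); Savitzky-Golay smoothing (frame 9, order 4 — implemented
in-package as the closed-form polynomial projection, since no signal
library is available, and tested by its defining property of preserving
degree ≤ 4 polynomials exactly).

`epoch_and_baseline()` cuts feedback-locked epochs on a half-open
$[-1, 6)$ s grid at 50 Hz — exactly **350 bins**, feedback onset at the
51st bin. A 350-bin count is arithmetically consistent only with the full 7 s
segment at 50 Hz, hence the half-open convention.
The mean of the 25 bins covering the 500 ms before feedback is stored as
the trial's baseline and subtracted from the whole epoch. The first five
trials (task-onset arousal transient) and the last trial (no 6 s of data)
are dropped at epoching, so preprocessing reports still reflect the whole
recording. `participant_exclusion()` flags participants whose interpolated
percentage exceeds the cohort mean by 2.5 SD — for pupil analyses only.

# Per-bin mixed models and cluster inference

For each of the 350 bins, the epoch value is modeled as baseline
(nuisance, always included) + predictors of interest + participant random
intercept; full and reduced models are fitted by **maximum likelihood**
(not REML — the compared fixed-effect structures differ) and compared by a
likelihood-ratio test against $\chi^2$. Because a cluster permutation run
needs $\sim 10^5$ such fits, the fitter is a profiled-ML random-intercept
engine written in C++ (1-D optimization over the variance ratio with
closed-form GLS coefficients via Sherman-Morrison); it reproduces
`lme4::lmer(REML = FALSE)` log-likelihoods to ~$10^{-6}$, including
boundary (singular) fits, and lme4 remains the oracle in the tests.
Rank-deficient bins are flagged and treated as non-significant.

Multiple comparisons across bins are handled by cluster-based permutation:
the predictors of interest are shuffled across trials *within participant*
(preserving participant-level exchangeability; the protocol does not state
the permutation unit), the per-bin LRT series is recomputed per
permutation, and observed runs of consecutive significant bins are kept
only if their length strictly exceeds the null threshold. Two null
summaries are available:

* `null_pool = "max"` (default): the ceiling$((B{+}1)p)$-th order
  statistic of the per-permutation **maximum** cluster lengths. By the
  usual randomization argument this bounds the family-wise error at
  $1-p$; an iid-world simulation in the acceptance suite confirms ~5%.
* `null_pool = "all"`: the 95th percentile of **all** null cluster
  lengths pooled across permutations, a variant seen in the pupillometry
  literature. It is kept for comparability but is anticonservative
  whenever permutations produce several clusters each (measured ~25%
  family-wise error on null cohorts), which is why it is not the default.

Even with the max statistic, a residual ~2% inflation was measured on
full-pipeline null cohorts (7.5% [3.9, 12.7] over 160 cohorts). Its source
is the task's own timing: the 7 s epoch exceeds the 6.4–8.5 s trial
spacing, so adjacent epochs share raw samples and the baseline window of
one trial overlaps the tail bins of the previous one, breaking strict
across-trial exchangeability of outcomes. This is a property of the
design being emulated, not of the implementation.

Three analysis frontends mirror the study's logic: a single-predictor test
(`cluster_permutation()`), the dual-basis model (`dual_basis_model()`)
with the identity basis $\Phi_0(q) = q$ and the entropy basis
$\Phi_1(q) = H(q)$ — implemented with the *positive* entropy sign, so a
positive coefficient means larger responses at higher uncertainty (the
entropy expression is sometimes written without the minus sign; the choice
only flips coefficient signs, not tests) — each basis tested by removing it from the
full model with its own permutation correction; and the dichotomized
interaction model (`dichotomized_interaction()`), which tests whether the
slope of $q$ differs below/above $q = 0.5$, the signature that separates a
genuine entropy-shaped (sign-flipping) effect from a linear one.

# Reproducibility

Every stochastic function takes an explicit integer seed;
`derive_seed()` hashes a master seed with string tags so that per-stage,
per-participant streams are independent and stable — enlarging a cohort
never changes existing participants. `run_study()` chains the whole
synthetic study from one config (JSON on disk; YAML is not available in
the supported environment) into a directory of plain-text artifacts plus a
manifest, with per-stage completion markers for resumability. The
`revlearn` CLI (`inst/cli/revlearn`) exposes the stages as subcommands.

# Known limitations

* The HMM likelihood is a Monte Carlo estimate; fitted shape parameters
  are weakly identified on single 100–150-trial sessions (the flat
  directions trade $\alpha_p$ against $\beta_p$); AIC comparisons and
  recovery are the supported use, per-parameter interpretation is not.
* The pooled-length cluster threshold is provided for comparability
  but should not be used for confirmatory claims (see above).
* `exact_posterior()` is exponential in $t$ and is an oracle, not an
  analysis path.
* Scripted agents and missing-response bookkeeping are supported in the
  session format, but the synthetic agents always respond; likelihood
  handling of missed trials (excluded from the product, state still
  advanced) follows the only interpretation consistent with the
  observation model.
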