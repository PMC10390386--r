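#' Prior parameters of the reversal hidden Markov model
#'
#' The model places a `Beta(alpha_a, beta_a)` prior on the per-transition
#' reversal probability and a `Beta(alpha_p, beta_p)` prior, truncated to
#' `[0.5, 1]`, on the probability that the correct side equals the preferred
#' side. Truncation guarantees that the latent "preferred" side really is
#' rewarded more often than not; it is what makes the `c` correction terms
#' necessary.
#'
#' @param alpha_p,beta_p positive shapes of the truncated beta prior on the
#'   preferred-side reward probability.
#' @param alpha_a,beta_a positive shapes of the beta prior on the reversal
#'   probability.
#' @return an object of class `hmm_params`.
#' @export
#' @examples
#' hmm_params(1, 1, 1, 10)
hmm_params <- function(alpha_p, beta_p, alpha_a, beta_a) {
  v <- c(alpha_p = alpha_p, beta_p = beta_p, alpha_a = alpha_a,
         beta_a = beta_a)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("all four shape parameters must be strictly positive and finite")
  }
  structure(as.list(v), class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(sprintf(
    "HMM priors: p ~ truncBeta(%.4g, %.4g) on [0.5,1]; a ~ Beta(%.4g, %.4g)\n",
    x$alpha_p, x$beta_p, x$alpha_a, x$beta_a))
  invisible(x)
}

#' Truncation correction for the first-trial observation predictive
#'
#' For the `[0.5, 1]`-truncated beta prior the beta-Bernoulli predictive picks
#' up an additive correction: `c0 = 0.5^(alpha_p + beta_p) /
#' (B(alpha_p, beta_p) - B(0.5; alpha_p, beta_p))`, where `B` is the beta
#' function and `B(0.5; ., .)` the (non-regularized) incomplete beta function.
#'
#' @param params an [hmm_params()] object.
#' @return positive scalar correction term.
#' @export
#' @examples
#' c0_correction(hmm_params(1, 1, 1, 1)) # 0.5
c0_correction <- function(params) {
  ap <- params$alpha_p
  bp <- params$beta_p
  bfull <- beta(ap, bp)
  blow <- pbeta(0.5, ap, bp) * bfull # non-regularized incomplete beta at 0.5
  den <- bfull - blow
  if (!is.finite(den) || den <= .Machine$double.eps * bfull) {
    stop("prior mass of p above 0.5 is numerically zero; ",
         "c0 correction is degenerate for these shapes")
  }
  c0 <- 0.5^(ap + bp) / den
  if (!is.finite(c0)) {
    stop("c0 correction overflowed; shapes too extreme")
  }
  c0
}

#' Binary Shannon entropy in bits
#'
#' `H(q) = -q log2 q - (1 - q) log2(1 - q)` with `0 log 0 := 0`. Maximal (1)
#' at `q = 0.5` and zero at `q = 0` or `1`; this single implementation is
#' shared by the filter's state entropy and the entropy basis function of the
#' pupil regression models.
#'
#' @param q probability (vectorized). `NA` propagates.
#' @return entropy in bits.
#' @export
#' @examples
#' binary_entropy(c(0, 0.25, 0.5, 1))
binary_entropy <- function(q) {
  if (any(q < 0 | q > 1, na.rm = TRUE)) {
    stop("`q` must lie in [0, 1]")
  }
  term <- function(p) ifelse(p > 0, -p * log2(p), 0)
  term(q) + term(1 - q)
}

#' State change probability for a chosen side
#'
#' The posterior probability that the current preferred side differs from the
#' reference choice: `P(z_t = 1 - y_t | x_{1:t})`.
#'
#' @param posterior_z1 posterior probability that side 1 is preferred
#'   (vectorized).
#' @param y choice in `{0, 1}`; `NA` (missed trial) propagates to `NA`.
#' @return probability that the state changed away from `y`.
#' @export
#' @examples
#' state_change_probability(0.9, 0) # 0.9
state_change_probability <- function(posterior_z1, y) {
  ifelse(is.na(y), NA_real_, ifelse(y == 1, 1 - posterior_z1, posterior_z1))
}

#' Initialize a particle set
#'
#' All particles start with the empty history: equal weights, no reversals, no
#' matches, and the truncation correction at its `c0` value.
#'
#' @param params an [hmm_params()] object.
#' @param n_particles number of particles (>= 1).
#' @return an object of class `particle_set`.
#' @export
init_particles <- function(params, n_particles) {
  if (!is.numeric(n_particles) || n_particles < 1) {
    stop("`n_particles` must be >= 1")
  }
  n <- as.integer(n_particles)
  structure(
    list(params = params, t = 0L, z = integer(n), r = numeric(n),
         m = numeric(n), c = rep(c0_correction(params), n),
         w = rep(1 / n, n)),
    class = "particle_set")
}

# transition probabilities P(z_t = 1), P(z_t = 0) per particle, for trial t
.trans_probs <- function(ps, t) {
  if (t == 1L) {
    list(p1 = rep(0.5, length(ps$z)), p0 = rep(0.5, length(ps$z)))
  } else {
    aa <- ps$params$alpha_a
    ba <- ps$params$beta_a
    tden <- aa + ba + (t - 2)
    stay <- (ba + (t - 2) - ps$r) / tden
    change <- (aa + ps$r) / tden
    p1 <- ifelse(ps$z == 1L, stay, change)
    list(p1 = p1, p0 = 1 - p1)
  }
}

#' Advance a particle set by one observed trial
#'
#' Branches every particle over the two possible current states, computes the
#' pre-observation predictive for the trial, conditions on the observed
#' correct side, renormalizes, and resamples back to the original particle
#' count. Uses the current R RNG stream; seed with `set.seed()` for
#' reproducibility.
#'
#' @param particles a `particle_set` from [init_particles()] or a previous
#'   step.
#' @param x_t observed correct side in `{0, 1}`.
#' @param resampler `"systematic"` (default, lower variance) or
#'   `"multinomial"`.
#' @return list with elements `particles` (advanced set) and `estimates`
#'   (one-row data frame: `trial`, `posterior_z0`, `posterior_z1`,
#'   `predictive_x0`, `predictive_x1`).
#' @export
filter_step <- function(particles, x_t,
                        resampler = c("systematic", "multinomial")) {
  resampler <- match.arg(resampler)
  if (!x_t %in% c(0L, 1L)) stop("`x_t` must be 0 or 1")
  ps <- particles
  p <- ps$params
  t <- ps$t + 1L
  n <- length(ps$z)
  obs_den <- p$alpha_p + p$beta_p + (t - 1)

  tr <- .trans_probs(ps, t)
  num_match <- p$alpha_p + ps$m + ps$c
  num_mis <- p$beta_p + (t - 1) - ps$m - ps$c
  pmatch <- pmin(pmax(num_match / obs_den, 0), 1)

  pred1 <- sum(ps$w * (tr$p1 * pmatch + tr$p0 * (1 - pmatch)))

  # branch z_t = 1 / z_t = 0, conditioned on x_t
  obs1 <- if (x_t == 1L) pmatch else 1 - pmatch
  obs0 <- if (x_t == 0L) pmatch else 1 - pmatch
  w1 <- ps$w * tr$p1 * obs1
  w0 <- ps$w * tr$p0 * obs0
  tot <- sum(w1) + sum(w0)
  if (tot <= 0) stop("all particle branches received zero probability")
  post1 <- sum(w1) / tot

  bw <- c(w1, w0) / tot
  bz <- rep(c(1L, 0L), each = n)
  br <- c(ps$r + as.numeric(t > 1L & ps$z != 1L),
          ps$r + as.numeric(t > 1L & ps$z != 0L))
  match1 <- as.numeric(x_t == 1L)
  bm <- c(ps$m + match1, ps$m + (1 - match1))
  cd1 <- if (x_t == 1L) num_match else num_mis
  cd0 <- if (x_t == 0L) num_match else num_mis
  bc <- c(0.5 * obs_den * ps$c / cd1, 0.5 * obs_den * ps$c / cd0)

  idx <- if (resampler == "systematic") {
    u <- (runif(1) + seq_len(n) - 1) / n
    findInterval(u, cumsum(bw)) + 1L
  } else {
    sample.int(2L * n, n, replace = TRUE, prob = bw)
  }
  idx <- pmin(idx, 2L * n)

  out <- structure(
    list(params = p, t = t, z = bz[idx], r = br[idx], m = bm[idx],
         c = bc[idx], w = rep(1 / n, n)),
    class = "particle_set")
  est <- data.frame(trial = t, posterior_z0 = 1 - post1, posterior_z1 = post1,
                    predictive_x0 = 1 - pred1, predictive_x1 = pred1)
  list(particles = out, estimates = est)
}

#' Run the particle filter over a session
#'
#' Produces per-trial posteriors over the preferred side, the pre-observation
#' predictive used by the softmax choice model, the state change probability
#' relative to the agent's choice, and the state entropy in bits. State
#' entropy equals the binary entropy of the state change probability (and of
#' the posterior itself, by symmetry).
#'
#' @param params an [hmm_params()] object.
#' @param session a session record (see [generate_session()]) or any data
#'   frame with columns `x` and optionally `y`.
#' @param n_particles number of particles; default 10000.
#' @param seed integer RNG seed for resampling.
#' @param resampler `"systematic"` or `"multinomial"`.
#' @param engine `"cpp"` (fast path) or `"r"` (reference [filter_step()]
#'   loop); both produce estimates of the same posterior.
#' @return data frame of class `trial_estimates`: `trial`, `posterior_z0`,
#'   `posterior_z1`, `state_change_probability`, `state_entropy`,
#'   `predictive_x0`, `predictive_x1`.
#' @export
run_filter <- function(params, session, n_particles = 10000, seed = 1L,
                       resampler = c("systematic", "multinomial"),
                       engine = c("cpp", "r")) {
  resampler <- match.arg(resampler)
  engine <- match.arg(engine)
  x <- as.integer(session$x)
  if (anyNA(x) || !all(x %in% c(0L, 1L))) {
    stop("session must provide x in {0,1} for every trial")
  }
  y <- if (!is.null(session$y)) session$y else rep(NA_integer_, length(x))

  if (engine == "cpp") {
    res <- with_seed(seed, hmm_filter_cpp(
      x, params$alpha_p, params$beta_p, params$alpha_a, params$beta_a,
      c0_correction(params), as.integer(n_particles),
      as.integer(resampler == "multinomial")))
    post1 <- res$posterior_z1
    pred1 <- res$predictive_x1
  } else {
    post1 <- pred1 <- numeric(length(x))
    ps <- init_particles(params, n_particles)
    with_seed(seed, for (t in seq_along(x)) {
      stp <- filter_step(ps, x[t], resampler)
      ps <- stp$particles
      post1[t] <- stp$estimates$posterior_z1
      pred1[t] <- stp$estimates$predictive_x1
    })
  }

  scp <- state_change_probability(post1, y)
  out <- data.frame(
    trial = seq_along(x),
    posterior_z0 = 1 - post1,
    posterior_z1 = post1,
    state_change_probability = scp,
    state_entropy = binary_entropy(post1),
    predictive_x0 = 1 - pred1,
    predictive_x1 = pred1)
  class(out) <- c("trial_estimates", "data.frame")
  out
}

#' Exact posterior by enumeration of hidden-state histories
#'
#' Sums the joint over all `2^t` hidden-state histories using the same
#' beta-Bernoulli recursions as the filter. Exponential in `t`; intended as
#' the oracle against which the particle approximation is checked.
#'
#' @param params an [hmm_params()] object.
#' @param x integer vector of observed correct sides, length <= 14.
#' @return list with `trials` (data frame: `trial`, `posterior_z0`,
#'   `posterior_z1`, `predictive_x1`) and `marginal` (the probability
#'   `P(x_{1:t})` of the observed sequence).
#' @export
exact_posterior <- function(params, x) {
  x <- as.integer(x)
  if (length(x) > 14) stop("enumeration limited to t <= 14")
  if (!all(x %in% c(0L, 1L))) stop("`x` must be 0/1")
  ap <- params$alpha_p
  bp <- params$beta_p
  aa <- params$alpha_a
  ba <- params$beta_a
  c0 <- c0_correction(params)

  z <- NA_integer_
  r <- 0
  m <- 0
  cc <- c0
  pr <- 1 # absolute joint probability P(z_{1:t-1}, x_{1:t-1})
  post1 <- pred1 <- numeric(length(x))

  for (t in seq_along(x)) {
    obs_den <- ap + bp + (t - 1)
    if (t == 1L) {
      tr1 <- tr0 <- rep(0.5, length(pr))
    } else {
      tden <- aa + ba + (t - 2)
      stay <- (ba + (t - 2) - r) / tden
      change <- (aa + r) / tden
      tr1 <- ifelse(z == 1L, stay, change)
      tr0 <- 1 - tr1
    }
    num_match <- ap + m + cc
    num_mis <- bp + (t - 1) - m - cc
    pmatch <- num_match / obs_den

    pred1[t] <- sum(pr * (tr1 * pmatch + tr0 * (1 - pmatch))) / sum(pr)

    obs1 <- if (x[t] == 1L) pmatch else 1 - pmatch
    obs0 <- if (x[t] == 0L) pmatch else 1 - pmatch
    w1 <- pr * tr1 * obs1
    w0 <- pr * tr0 * obs0
    post1[t] <- sum(w1) / (sum(w1) + sum(w0))

    match1 <- as.numeric(x[t] == 1L)
    cd1 <- if (x[t] == 1L) num_match else num_mis
    cd0 <- if (x[t] == 0L) num_match else num_mis
    pr <- c(w1, w0)
    r <- c(r + as.numeric(t > 1L & z != 1L),
           r + as.numeric(t > 1L & z != 0L))
    m <- c(m + match1, m + (1 - match1))
    cc <- c(0.5 * obs_den * cc / cd1, 0.5 * obs_den * cc / cd0)
    z <- rep(c(1L, 0L), each = length(w1))
  }

  list(trials = data.frame(trial = seq_along(x), posterior_z0 = 1 - post1,
                           posterior_z1 = post1, predictive_x1 = pred1),
       marginal = sum(pr))
}
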