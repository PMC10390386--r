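test_that("softmax choice rule matches hand evaluation and is overflow-safe", {
  expect_equal(softmax_choice(c(0.7, 0.3), 0), c(0.5, 0.5))
  expect_equal(softmax_choice(c(0.7, 0.3), Inf), c(1, 0))
  expect_equal(softmax_choice(c(0.6, 0.4), 5),
               c(exp(3), exp(2)) / (exp(3) + exp(2)), tolerance = 1e-12)
  expect_equal(softmax_choice(c(0.6, 0.4), 5)[1], 0.7311, tolerance = 1e-4)
  big <- softmax_choice(c(1e4, 0), 100)
  expect_false(anyNA(big))
  expect_equal(sum(big), 1)
  expect_error(softmax_choice(c(1, 0), -1), ">= 0")
})

test_that("Rescorla-Wagner update touches only the chosen side", {
  expect_equal(rw_update(c(0.5, 0.5), 1, 1, 0.1), c(0.5, 0.55))
  expect_equal(rw_update(c(0.4, 0.6), 0, 0, 0), c(0.4, 0.6))
  expect_equal(rw_update(c(0.4, 0.6), 0, 1, 1), c(1, 0.6))
  expect_error(rw_update(c(0.5, 0.5), 1, 1, 1.5), "0, 1")
})

test_that("no-reversal predictive equals the beta-Bernoulli closed form", {
  expect_equal(no_reversal_predictive(2, c(1, 1))[2], 2 / 3)
  # pseudo-count form: P(x_t=1 | x_{1:t-1}) = (s/2 + sum(x)) / (s + t - 1)
  set.seed(5)
  for (s in c(0.5, 2, 10)) {
    x <- rbinom(30, 1, 0.7)
    pred <- no_reversal_predictive(s, x)
    closed <- (s / 2 + c(0, cumsum(x)[-30])) / (s + 0:29)
    expect_equal(pred, closed, tolerance = 1e-12)
  }
  long <- no_reversal_predictive(2, rep(1, 500))
  expect_gt(long[500], 0.99)
  alt <- no_reversal_predictive(2, rep(c(1, 0), 100))
  expect_lt(abs(alt[200] - 0.5), 0.01)
  expect_error(no_reversal_predictive(0, c(1)), "> 0")
})

test_that("session NLL reduces to n log 2 for random choice and respects missing trials", {
  s <- generate_session(condition_config("exp2a"), rw_agent(), seed = 3)
  n <- sum(!is.na(s$y))
  for (spec in list(list("rescorla_wagner", c(alpha = 0.3, beta = 0)),
                    list("no_reversal", c(alpha_sum = 2, beta = 0)),
                    list("hmm", c(alpha_p = 1, beta_p = 1, alpha_a = 1,
                                  beta_a = 6, beta = 0)))) {
    expect_equal(session_nll(spec[[1]], spec[[2]], s), n * log(2),
                 tolerance = 1e-9)
  }
  one <- manual_session(0L, 0L, 0L)
  expect_equal(session_nll("rescorla_wagner", c(alpha = 0.3, beta = 4), one),
               log(2), tolerance = 1e-9)
  # a missed trial drops out of the likelihood but advances the state
  z <- rep(0L, 6)
  full <- manual_session(z, z, rep(0L, 6))
  miss <- full
  miss$y[3] <- NA
  th <- c(alpha_sum = 2, beta = 5)
  nll_full <- session_nll("no_reversal", th, full)
  nll_miss <- session_nll("no_reversal", th, miss)
  pred <- no_reversal_predictive(2, z)
  p3 <- 1 - stats::plogis(5 * (2 * pred[3] - 1))
  expect_equal(nll_miss, nll_full + log(p3), tolerance = 1e-9)
})

test_that("particle-filter NLL matches the exact-oracle NLL on toy sessions", {
  set.seed(11)
  p <- c(alpha_p = 1, beta_p = 1, alpha_a = 1, beta_a = 4, beta = 6)
  for (rep in 1:2) {
    x <- rbinom(9, 1, 0.6)
    y <- rbinom(9, 1, 0.5)
    s <- manual_session(rep(0L, 9), x, y)
    ex <- exact_posterior(hmm_params(1, 1, 1, 4), x)$trials
    p1 <- stats::plogis(6 * (2 * ex$predictive_x1 - 1))
    oracle_nll <- -sum(log(ifelse(y == 1, p1, 1 - p1)))
    pf_nll <- session_nll("hmm", p, s, n_particles = 1e5, seed = rep)
    expect_equal(pf_nll, oracle_nll, tolerance = 0.05)
  }
})

test_that("likelihood is invariant under global left/right relabeling", {
  s <- generate_session(condition_config("exp2b"), rw_agent(), seed = 6)
  flip <- s
  flip$x <- 1L - flip$x
  flip$y <- 1L - flip$y
  flip$z <- 1L - flip$z
  for (spec in list(list("rescorla_wagner", c(alpha = 0.4, beta = 3)),
                    list("no_reversal", c(alpha_sum = 3, beta = 3)))) {
    expect_equal(session_nll(spec[[1]], spec[[2]], s),
                 session_nll(spec[[1]], spec[[2]], flip), tolerance = 1e-10)
  }
})

test_that("information criteria identities hold and fits are deterministic", {
  expect_equal(2 * 5 + 2 * 100, 210) # AIC arithmetic, k = 5, nll = 100
  s <- generate_session(condition_config("exp2a"), rw_agent(), seed = 8)
  spec <- fit_spec("rescorla_wagner", n_starts = 3, seed = 21)
  f1 <- fit_mle(spec, s)
  f2 <- fit_mle(spec, s)
  expect_identical(f1$theta, f2$theta)
  expect_equal(f1$aic, 2 * f1$k + 2 * f1$nll)
  expect_equal(f1$bic, f1$k * log(f1$n_obs) + 2 * f1$nll)
  expect_gte(f1$nll, 0)
  expect_equal(f1$n_obs, sum(!is.na(s$y)))
})

test_that("RW parameters are recoverable from simulated sessions", {
  cfg <- task_config(150, 0.75, "stochastic", h = 0.06)
  true_alpha <- seq(0.15, 0.75, length.out = 6)
  fitted <- vapply(seq_along(true_alpha), function(i) {
    s <- generate_session(cfg, rw_agent(alpha = true_alpha[i], beta = 8),
                          seed = 100 + i)
    fit_mle(fit_spec("rescorla_wagner", n_starts = 3, seed = i),
            s)$theta[["alpha"]]
  }, numeric(1))
  expect_gt(cor(true_alpha, fitted, method = "spearman"), 0.5)
  expect_lt(mean(abs(fitted - true_alpha)), 0.2)
})

test_that("generative check returns summaries and curves, and degenerate input is empty", {
  gc0 <- generative_check("rescorla_wagner", list(), condition_config("exp2a"))
  expect_equal(nrow(gc0$summaries), 0)
  gc <- generative_check("rescorla_wagner",
                         list(c(alpha = 0.35, beta = 8)),
                         condition_config("exp2a"), n_per_fit = 4, seed = 2)
  expect_equal(nrow(gc$summaries), 4)
  expect_true(all(c("preferred_pct", "rewarded_pct", "switch_pct") %in%
                    names(gc$summaries)))
  expect_false(is.null(gc$curves))
})
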