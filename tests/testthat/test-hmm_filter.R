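test_that("c0 correction matches hand evaluation and the integration oracle", {
  expect_equal(c0_correction(hmm_params(1, 1, 1, 1)), 0.5)

  # Eq-7-style first-trial branch equals 0.5 * E[p] under the truncated
  # prior, with E[p] from numerical integration (independent oracle)
  for (shapes in list(c(1, 1), c(2, 3), c(5, 2))) {
    p <- hmm_params(shapes[1], shapes[2], 1, 1)
    c0 <- c0_correction(p)
    mass <- 1 - pbeta(0.5, shapes[1], shapes[2])
    ep <- integrate(function(v) v * dbeta(v, shapes[1], shapes[2]) / mass,
                    0.5, 1)$value
    branch <- 0.5 * (shapes[1] + c0) / (shapes[1] + shapes[2])
    expect_equal(branch, 0.5 * ep, tolerance = 1e-8)
  }
  expect_equal(0.5 * (1 + c0_correction(hmm_params(1, 1, 1, 1))) / 2, 0.375)

  # prior with essentially no mass above 0.5 is degenerate
  expect_error(c0_correction(hmm_params(0.001, 1000, 1, 1)), "degenerate")
  expect_error(hmm_params(-1, 1, 1, 1), "positive")
})

test_that("binary entropy matches its closed form", {
  expect_equal(binary_entropy(0.5), 1)
  expect_equal(binary_entropy(0), 0)
  expect_equal(binary_entropy(1), 0)
  expect_equal(binary_entropy(0.25), 0.8113, tolerance = 1e-4)
  expect_equal(binary_entropy(c(0.3, 0.7)), rep(binary_entropy(0.3), 2))
  expect_error(binary_entropy(1.2), "0, 1")
})

test_that("state change probability is the posterior complement of the choice", {
  expect_equal(state_change_probability(0.9, 1), 0.1)
  expect_equal(state_change_probability(0.9, 0), 0.9)
  expect_equal(state_change_probability(0.5, 1), 0.5)
  expect_equal(state_change_probability(0.8, NA), NA_real_)
})

test_that("particle initialization and the first transition predictive are correct", {
  p <- hmm_params(1, 1, 1, 1)
  ps <- init_particles(p, 100)
  expect_equal(ps$w, rep(0.01, 100))
  expect_equal(ps$t, 0L)
  expect_equal(ps$c, rep(0.5, 100))
  expect_no_error(init_particles(p, 1))
  expect_error(init_particles(p, 0), ">= 1")

  # beta-binomial transition predictive after one trial: change probability
  # (alpha_a + r) / (alpha_a + beta_a + t - 1) = 1/2 for unit shapes, r = 0
  stepped <- with_seed_for_tests(1, filter_step(ps, 1L))$particles
  tr <- revlearn:::.trans_probs(stepped, 2L)
  chg <- ifelse(stepped$z == 1L, tr$p0, tr$p1)
  expect_equal(chg, rep(0.5, 100))
})

test_that("particle filter agrees with the exact enumeration oracle", {
  set.seed(20)
  for (rep in 1:3) {
    p <- hmm_params(exp(runif(1, -0.5, 1)), exp(runif(1, -0.5, 1)),
                    exp(runif(1, -1, 0.5)), exp(runif(1, 0, 2)))
    x <- rbinom(10, 1, 0.6)
    ex <- exact_posterior(p, x)$trials
    pf <- run_filter(p, data.frame(x = x), n_particles = 1e5, seed = rep)
    expect_lt(max(abs(pf$posterior_z1 - ex$posterior_z1)), 0.01)
    expect_lt(max(abs(pf$predictive_x1 - ex$predictive_x1)), 0.01)
  }
  # the reference R engine estimates the same posterior
  p <- hmm_params(1, 1, 1, 1)
  x <- c(1, 1, 0, 1)
  ex <- exact_posterior(p, x)$trials
  pr <- run_filter(p, data.frame(x = x), n_particles = 2e4, seed = 1,
                   engine = "r")
  expect_lt(max(abs(pr$posterior_z1 - ex$posterior_z1)), 0.02)
})

test_that("exact oracle marginals are a probability distribution over sequences", {
  p <- hmm_params(2, 1.5, 0.8, 4)
  seqs <- expand.grid(rep(list(0:1), 4))
  tot <- sum(apply(seqs, 1, function(x) exact_posterior(p, x)$marginal))
  expect_equal(tot, 1, tolerance = 1e-10)
  # t = 1 prior state probability is 0.5 before any observation: the
  # predictive for the first trial carries no side information
  expect_equal(exact_posterior(p, 1)$trials$predictive_x1, 0.5)
})

test_that("posterior favors the observed side monotonically without negative feedback", {
  p <- hmm_params(1, 1, 1, 6)
  ex <- exact_posterior(p, rep(1L, 8))$trials
  expect_true(all(diff(ex$posterior_z1) > 0))
  # state change probability relative to the constant choice y = 1
  scp <- state_change_probability(ex$posterior_z1, rep(1L, 8))
  expect_true(all(diff(scp) < 0))
})

test_that("relabeling symmetry: complementing x mirrors posteriors", {
  p <- hmm_params(1.7, 1.2, 0.9, 5)
  x <- c(1, 0, 1, 1, 1, 0)
  a <- exact_posterior(p, x)$trials
  b <- exact_posterior(p, 1 - x)$trials
  expect_equal(a$posterior_z1, b$posterior_z0, tolerance = 1e-12)
  expect_equal(a$predictive_x1, 1 - b$predictive_x1, tolerance = 1e-12)
  expect_equal(binary_entropy(a$posterior_z1), binary_entropy(b$posterior_z1),
               tolerance = 1e-12)
})

test_that("run_filter output satisfies its invariants and is reproducible", {
  p <- hmm_params(1, 1, 1, 12)
  s <- generate_session(condition_config("exp2a"), rw_agent(), seed = 2)
  a <- run_filter(p, s, n_particles = 5000, seed = 9)
  b <- run_filter(p, s, n_particles = 5000, seed = 9)
  expect_identical(a, b)
  expect_equal(a$posterior_z0 + a$posterior_z1, rep(1, nrow(a)))
  expect_true(all(a$state_entropy >= 0 & a$state_entropy <= 1))
  expect_equal(a$state_entropy,
               binary_entropy(a$state_change_probability))
  expect_error(run_filter(p, data.frame(x = c(0, NA))), "every trial")
})

test_that("negative feedback after a long rewarded run raises both uncertainty signals", {
  p <- hmm_params(1, 1, 1, 12)
  x <- c(rep(1L, 12), 0L)
  y <- rep(1L, 13)
  est <- run_filter(p, data.frame(x = x, y = y), n_particles = 5e4,
                    seed = 4)
  t0 <- 12
  expect_gt(est$state_change_probability[13],
            est$state_change_probability[t0])
  expect_gt(est$state_entropy[13], est$state_entropy[t0])
})

test_that("the alpha_a -> 0 limit reduces to the closed-form no-reversal recursion", {
  # symmetric shape priors: the mirrored halves of the truncated prior tile
  # the full beta, so the closed form is exact in the limit
  x <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0)
  for (shape in c(1, 2)) {
    p <- hmm_params(shape, shape, 1e-6, 1e6)
    ex <- exact_posterior(p, x)$trials
    expect_lt(max(abs(ex$predictive_x1 -
                        no_reversal_predictive(2 * shape, x))), 1e-3)
  }
})
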