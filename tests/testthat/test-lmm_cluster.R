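sim_lmm_data <- function(n_g = 8, n_per = 30, beta_x = 0, sd_b = 0.4,
                         sd_e = 0.7, seed = 1) {
  with_seed_for_tests(seed, {
    g <- rep(seq_len(n_g), each = n_per)
    x <- runif(n_g * n_per)
    b <- rnorm(n_g, 0, sd_b)
    y <- 1 + beta_x * x + b[g] + rnorm(n_g * n_per, 0, sd_e)
    list(y = y, x = x, g = g)
  })
}

test_that("the fast profiled-ML fitter reproduces lme4 (interior and boundary)", {
  d <- as.data.frame(sim_lmm_data(beta_x = 0.8, seed = 2))
  f <- lmm_ml(cbind(1, d$x), d$y, d$g)
  m <- lme4::lmer(y ~ x + (1 | g), data = d, REML = FALSE)
  expect_equal(f$logLik, as.numeric(logLik(m)), tolerance = 1e-6)
  expect_equal(unname(f$beta), unname(lme4::fixef(m)), tolerance = 1e-5)

  # boundary (singular) case: no participant variance
  d0 <- as.data.frame(sim_lmm_data(beta_x = 0.8, sd_b = 0, seed = 3))
  f0 <- lmm_ml(cbind(1, d0$x), d0$y, d0$g)
  m0 <- suppressMessages(lme4::lmer(y ~ x + (1 | g), data = d0,
                                    REML = FALSE))
  expect_equal(f0$logLik, as.numeric(logLik(m0)), tolerance = 1e-6)
})

test_that("LRT statistics are invariant to affine predictor rescaling", {
  d <- sim_lmm_data(beta_x = 0.5, seed = 4)
  Xr <- cbind(1)
  ll_red <- lmm_ml(matrix(1, length(d$y)), d$y, d$g)$logLik
  s1 <- lmm_ml(cbind(1, d$x), d$y, d$g)$logLik
  s2 <- lmm_ml(cbind(1, 1000 * d$x + 7), d$y, d$g)$logLik
  expect_equal(2 * (s1 - ll_red), 2 * (s2 - ll_red), tolerance = 1e-5)
})

test_that("per-bin series flags rank-deficient designs instead of failing", {
  d <- sim_lmm_data(seed = 5)
  ll <- revlearn:::lmm_ml_bins_cpp(cbind(d$y), list(cbind(1, d$x, d$x)),
                                   as.integer(d$g) - 1L, max(d$g))
  expect_true(is.na(ll[1, 1]))
})

test_that("type-I rate of per-bin LRTs is near nominal on a null cohort", {
  # independent-noise outcome at each bin, predictor unrelated by design
  with_seed_for_tests(6, {
    n_g <- 8; n_per <- 25; nb <- 350
    g <- rep(seq_len(n_g), each = n_per)
    x <- runif(n_g * n_per)
    bl <- rnorm(n_g * n_per)
    b <- rnorm(n_g, 0, 0.3)
    Y <- matrix(rnorm(n_g * n_per * nb, sd = 0.5) + b[g], ncol = nb)
    epochs <- data.frame(
      participant = rep(g, nb), trial = rep(seq_len(n_g * n_per), nb),
      bin = rep(seq_len(nb), each = n_g * n_per), value = as.vector(Y),
      baseline = rep(bl, nb), pred = rep(x, nb))
    res <- fit_bin_series(epochs, bin_model_spec("pred"))
    rate <- mean(res$p < 0.05, na.rm = TRUE)
    expect_gt(rate, 0.01)
    expect_lt(rate, 0.11) # ~5% of 350 quasi-independent bins
  })
})

test_that("an injected change-probability effect yields a positive coefficient and a surviving cluster", {
  co <- make_pupil_cohort(6, b_changeprob = 0.6, seed = 31)
  res <- cluster_permutation(co, bin_model_spec("state_change_probability"),
                             n_perm = 60, seed = 7)
  expect_true(cluster_hits_kernel(res))
  # determinism
  res2 <- cluster_permutation(co, bin_model_spec("state_change_probability"),
                              n_perm = 60, seed = 7)
  expect_identical(res$threshold, res2$threshold)
  expect_identical(res$clusters, res2$clusters)
  # surviving clusters all exceed the threshold
  expect_true(all(res$clusters$length[res$clusters$surviving] >
                    res$threshold))
  # coefficient sign during the kernel support, from the dual-basis report
  db <- dual_basis_model(co, n_perm = 20, seed = 8)
  kern <- db$linear$series$bin %in% 75:150
  expect_gt(mean(db$linear$series$coef[kern], na.rm = TRUE), 0)
})

test_that("degenerate predictor distributions raise informative errors", {
  co <- make_pupil_cohort(2, seed = 32)
  co$state_change_probability <- 0.5
  expect_error(dual_basis_model(co, n_perm = 5), "constant")
  co$state_change_probability <- 0.2
  expect_error(dichotomized_interaction(co, n_perm = 5), "both sides")
  expect_error(cluster_permutation(co, bin_model_spec("state_entropy"),
                                   n_perm = 0), "n_perm")
})

test_that("an entropy-shaped effect is detected as the 0.5-dichotomized interaction", {
  co <- make_pupil_cohort(8, b_entropy = 0.7, seed = 33)
  expect_gt(mean(co$state_change_probability > 0.5), 0.02)
  res <- dichotomized_interaction(co, n_perm = 60, seed = 9)
  expect_true(cluster_hits_kernel(res))
})
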