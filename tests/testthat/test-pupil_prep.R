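test_that("Savitzky-Golay filter exactly preserves low-order polynomials", {
  t <- seq(-1, 1, length.out = 80)
  for (deg in 0:4) {
    y <- t^deg + 0.5 * t
    expect_equal(sgolay_filter(y, 9, 4), y, tolerance = 1e-9)
  }
  # degree 5 is not preserved
  y5 <- t^5
  expect_gt(max(abs(sgolay_filter(y5, 9, 4) - y5)), 1e-8)
  expect_error(sgolay_filter(t, 8, 4), "odd")
  expect_error(sgolay_filter(t, 9, 9), "<")
})

test_that("a constant recording cleans to a constant with zero interpolation", {
  rec <- constant_recording(4)
  cl <- clean_series(rec)
  expect_equal(cl$value_mm, rep(4, length(cl$value_mm)))
  expect_equal(cl$interpolated_pct, 0)
  expect_equal(length(cl$value_mm), floor(nrow(rec$samples) / 5))
})

test_that("an isolated spike is deleted with 10-sample padding on each side", {
  rec <- constant_recording(4, dur_s = 40)
  i <- 3000
  rec$samples$left_mm[i] <- rec$samples$right_mm[i] <- 10
  cl <- clean_series(rec)
  # 21 deleted 250 Hz samples (spike +/- 10) span 5 or 6 output blocks
  n_gap <- sum(cl$interpolated)
  expect_gte(n_gap, 4)
  expect_lte(n_gap, 6)
  gap_bins <- which(cl$interpolated)
  expect_true(all(abs(gap_bins - i / 5) <= 4))
  # values are restored by interpolation between constant neighbors
  expect_equal(cl$value_mm, rep(4, length(cl$value_mm)), tolerance = 1e-9)
})

test_that("a blink gap in a linear ramp is interpolated back onto the ramp", {
  rec <- constant_recording(0, dur_s = 40)
  ramp <- 3 + 0.01 * rec$samples$time_s
  rec$samples$left_mm <- rec$samples$right_mm <- ramp
  span <- 4000:4025 # ~100 ms blink
  rec$samples$left_blink[span] <- TRUE
  rec$samples$left_mm[span] <- NA
  cl <- clean_series(rec)
  expect_gt(sum(cl$interpolated), 0)
  # partial blocks at the gap edge use missing-aware means, so values there
  # sit within ~2 ms worth of slope of the true ramp
  expect_lt(max(abs(cl$value_mm - (3 + 0.01 * cl$time_s))), 1e-4)
})

test_that("a blink in one eye suffices for deletion and eyes are averaged", {
  rec <- constant_recording(4, dur_s = 20)
  rec$samples$left_mm <- rec$samples$left_mm + 0.2
  cl <- clean_series(rec)
  expect_equal(cl$value_mm, rep(4.1, length(cl$value_mm)))
})

test_that("cleaning is idempotent on already-clean smooth data", {
  rec <- constant_recording(0, dur_s = 30, fs = 50)
  tt <- rec$samples$time_s
  sig <- 4 + 0.02 * tt + 0.001 * tt^2
  rec$samples$left_mm <- rec$samples$right_mm <- sig
  cl1 <- clean_series(rec)
  rec2 <- rec
  rec2$samples <- data.frame(time_s = cl1$time_s, left_mm = cl1$value_mm,
                             right_mm = cl1$value_mm,
                             left_blink = FALSE, right_blink = FALSE)
  cl2 <- clean_series(rec2)
  expect_equal(cl2$value_mm, cl1$value_mm, tolerance = 1e-9)
})

test_that("epoching yields exactly 350 zero-baselined bins and drops 6 trials", {
  se_session <- generate_session(condition_config("exp2a"), rw_agent(),
                                 seed = 12)
  est <- run_filter(hmm_params(1, 1, 1, 12), se_session,
                    n_particles = 500, seed = 13)
  rec <- generate_recording(pupil_gen_spec(), se_session, est, seed = 14)
  cl <- clean_series(rec)
  ep <- epoch_and_baseline(cl, rec$events)
  expect_equal(ep$n_bins, 350)
  expect_equal(length(unique(ep$epochs$trial)), 94) # 100 - 5 first - last
  expect_false(any(c(1:5, 100) %in% ep$epochs$trial))
  expect_equal(unname(table(ep$epochs$trial)[1]), 350L)
  # baseline window (25 bins in [-0.5, 0)) mean is 0 for every epoch
  bw <- ep$epochs[ep$epochs$time_s >= -0.5 & ep$epochs$time_s < 0, ]
  expect_equal(as.vector(tapply(bw$bin, bw$trial, length)),
               rep(25L, 94))
  expect_lt(max(abs(tapply(bw$value, bw$trial, mean))), 1e-10)
  expect_equal(range(ep$epochs$time_s), c(-1, 6 - 0.02))
})

test_that("constant input gives all-zero epochs and exact interpolation accounting", {
  rec <- constant_recording(4, dur_s = 80, n_trials = 8, first_onset = 10,
                            onset_step = 8)
  cl <- clean_series(rec)
  ep <- epoch_and_baseline(cl, rec$events)
  expect_equal(unique(ep$epochs$value), 0)
  expect_equal(length(unique(ep$epochs$trial)), 2) # 8 - 5 - 1

  # interpolated percentage is exact on a constructed 50 Hz fixture
  rec50 <- constant_recording(4, dur_s = 20, fs = 50)
  k <- c(101:110, 301:305)
  rec50$samples$left_blink[k] <- rec50$samples$right_blink[k] <- TRUE
  cl50 <- clean_series(rec50)
  expect_equal(cl50$interpolated_pct, 100 * length(k) / length(cl50$value_mm))
})

test_that("epoch windows beyond the recording raise an error", {
  rec <- constant_recording(4, dur_s = 30, n_trials = 7, first_onset = 5,
                            onset_step = 4)
  cl <- clean_series(rec)
  expect_error(epoch_and_baseline(cl, rec$events), "exceeds")
})

test_that("participant exclusion applies the 2.5 SD rule to pupil analyses only", {
  expect_equal(participant_exclusion(rep(5, 6)), rep(FALSE, 6))
  pct <- c(5.1, 6, 5.5, 6.2, 5.8, 5.3, 6.1, 5.6, 5.9, 5.2, 5.7, 25)
  flags <- participant_exclusion(pct)
  expect_equal(which(flags), 12L)
  expect_gt(pct[12], mean(pct) + 2.5 * sd(pct))
  expect_error(participant_exclusion(5), "two participants")
})
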