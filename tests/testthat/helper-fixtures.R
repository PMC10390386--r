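# Shared fixture builders. Everything is generated in code at test time.

with_seed_for_tests <- function(seed, expr) {
  revlearn:::with_seed(seed, expr)
}

# a session data frame built by hand (for unit tests of summaries/epochs)
manual_session <- function(z, x, y, onset_step = 8) {
  n <- length(z)
  structure(
    data.frame(trial = seq_len(n), z = z, x = x, y = y,
               reward = ifelse(is.na(y), 0, ifelse(y == x, 1, -1)),
               reversal = c(FALSE, z[-1] != z[-n]),
               feedback_onset_s = seq_len(n) * onset_step,
               score = 100 + cumsum(ifelse(is.na(y), 0,
                                           ifelse(y == x, 1, -1)))),
    class = c("session_record", "data.frame"))
}

rw_agent <- function(alpha = 0.3, beta = 8) {
  agent_spec("rescorla_wagner", c(alpha = alpha, beta = beta))
}

# a constant-signal two-eye recording for preprocessing unit tests
constant_recording <- function(value = 4, dur_s = 60, fs = 250,
                               n_trials = 5, first_onset = 10,
                               onset_step = 9) {
  tt <- seq(0, dur_s, by = 1 / fs)
  n <- length(tt)
  structure(list(
    samples = data.frame(time_s = tt, left_mm = rep(value, n),
                         right_mm = rep(value, n),
                         left_blink = rep(FALSE, n),
                         right_blink = rep(FALSE, n)),
    events = data.frame(trial = seq_len(n_trials),
                        feedback_onset_s = first_onset +
                          onset_step * (seq_len(n_trials) - 1),
                        feedback_sign = 1L),
    baseline_mm = value, sample_rate = fs),
    class = "raw_pupil_recording")
}

# full synthetic cohort -> long epochs table ready for the LMM module
make_pupil_cohort <- function(n_pp, b_feedback = 0, b_changeprob = 0,
                              b_entropy = 0, seed = 1,
                              condition = "exp2a", n_particles = 1000,
                              hmm = hmm_params(1, 1, 1, 12),
                              agent = rw_agent()) {
  cfg <- condition_config(condition)
  spec <- pupil_gen_spec(b_feedback = b_feedback,
                         b_changeprob = b_changeprob,
                         b_entropy = b_entropy)
  out <- vector("list", n_pp)
  for (i in seq_len(n_pp)) {
    s <- generate_session(cfg, agent, seed = derive_seed(seed, "sess", i))
    est <- run_filter(hmm, s, n_particles = n_particles,
                      seed = derive_seed(seed, "filt", i))
    rec <- generate_recording(spec, s, est,
                              seed = derive_seed(seed, "pup", i))
    cl <- clean_series(rec)
    ep <- epoch_and_baseline(cl, rec$events)$epochs
    ep$participant <- i
    ep$state_change_probability <-
      est$state_change_probability[match(ep$trial, est$trial)]
    ep$state_entropy <- est$state_entropy[match(ep$trial, est$trial)]
    ep$feedback_negative <- as.numeric(s$reward[match(ep$trial, s$trial)] < 0)
    out[[i]] <- ep
  }
  do.call(rbind, out)
}

# does any surviving cluster overlap the evoked-response support
# (feedback onset is bin 51; the kernel peaks ~1 s = bin 101)?
cluster_hits_kernel <- function(result, lo = 55, hi = 250) {
  surv <- result$clusters[result$clusters$surviving, , drop = FALSE]
  nrow(surv) > 0 && any(surv$start <= hi & surv$end >= lo)
}
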