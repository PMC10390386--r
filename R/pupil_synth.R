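#' Specification of the synthetic pupil generator
#'
#' Defines the stated world of the synthetic recordings: a 250 Hz two-eye
#' pupil stream with a participant-level baseline, a feedback-locked evoked
#' response whose amplitude is a linear function of feedback valence, state
#' change probability and state entropy, AR(1) background noise, independent
#' per-eye measurement noise, and blink gaps.
#'
#' @param sample_rate Hz (default 250, the eye-tracker's rate).
#' @param baseline_mean,baseline_sd participant baseline diameter in mm
#'   (defaults 4 and 0.3; the baseline for one recording is drawn once).
#' @param kernel_shape,kernel_scale gamma-density evoked-response kernel;
#'   defaults shape 3, scale 0.5 s put the peak at 1 s post-feedback. The
#'   kernel is normalized to unit peak so the effect weights are in mm.
#' @param b_feedback mm added to the amplitude on negative feedback.
#' @param b_changeprob,b_entropy mm per unit of state change probability /
#'   state entropy.
#' @param ar_coef,ar_sd AR(1) coefficient (|.| < 1) and innovation SD (mm) of
#'   the common slow noise. The defaults give a marginal SD of ~0.25 mm,
#'   matching the slow arousal fluctuations of real recordings; much smaller
#'   values are unrealistic and make the 3 SD outlier rule clip the peaks of
#'   large evoked responses (a censoring artifact).
#' @param eye_sd independent white measurement noise per eye (mm).
#' @param blink_rate blinks per second (default 0.2).
#' @param blink_dur_range blink duration range in seconds (uniform draw).
#' @param drift_sd optional slow random-walk drift innovation SD (default 0,
#'   off, to keep baseline-correction tests clean).
#' @return an object of class `pupil_gen_spec`.
#' @export
pupil_gen_spec <- function(sample_rate = 250, baseline_mean = 4,
                           baseline_sd = 0.3, kernel_shape = 3,
                           kernel_scale = 0.5, b_feedback = 0.2,
                           b_changeprob = 0.3, b_entropy = 0.3,
                           ar_coef = 0.99, ar_sd = 0.035, eye_sd = 0.03,
                           blink_rate = 0.2, blink_dur_range = c(0.1, 0.4),
                           drift_sd = 0) {
  if (sample_rate <= 0) stop("`sample_rate` must be positive")
  if (abs(ar_coef) >= 1) stop("`ar_coef` must satisfy |coef| < 1")
  if (any(blink_dur_range <= 0)) stop("blink durations must be positive")
  structure(list(sample_rate = sample_rate, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, kernel_shape = kernel_shape,
                 kernel_scale = kernel_scale, b_feedback = b_feedback,
                 b_changeprob = b_changeprob, b_entropy = b_entropy,
                 ar_coef = ar_coef, ar_sd = ar_sd, eye_sd = eye_sd,
                 blink_rate = blink_rate, blink_dur_range = blink_dur_range,
                 drift_sd = drift_sd),
            class = "pupil_gen_spec")
}

# unit-peak gamma-density kernel evaluated at lag seconds
.pupil_kernel <- function(lag, shape, scale) {
  mode <- (shape - 1) * scale
  peak <- stats::dgamma(mode, shape = shape, scale = scale)
  ifelse(lag > 0, stats::dgamma(lag, shape = shape, scale = scale) / peak, 0)
}

#' Generate a raw two-eye pupil recording for one session
#'
#' The common signal is `baseline + sum_trials kernel(t - onset) * amplitude`
#' plus AR(1) noise, where the trial amplitude is
#' `b_feedback * 1{negative feedback} + b_changeprob * q_t + b_entropy * H_t`
#' using the model estimates supplied. Each eye adds independent white noise;
#' blinks are inserted as missing runs with flags (usually binocular, with a
#' small fraction affecting one eye).
#'
#' @param spec a [pupil_gen_spec()].
#' @param session a `session_record` (feedback onsets are taken from it).
#' @param estimates matching `trial_estimates` from [run_filter()]; rows are
#'   aligned to trials. Trials with missing state change probability
#'   contribute only the feedback term.
#' @param seed integer RNG seed.
#' @return list of class `raw_pupil_recording`: `samples` data frame
#'   (`time_s`, `left_mm`, `right_mm`, `left_blink`, `right_blink`), `events`
#'   data frame (`trial`, `feedback_onset_s`, `feedback_sign`), and the
#'   drawn `baseline_mm`.
#' @export
generate_recording <- function(spec, session, estimates, seed) {
  if (nrow(session) != nrow(estimates)) {
    stop("session and estimates must be aligned trial for trial")
  }
  with_seed(seed, {
    fs <- spec$sample_rate
    t_end <- max(session$feedback_onset_s) + 8
    tt <- seq(0, t_end, by = 1 / fs)
    n <- length(tt)

    base <- spec$baseline_mean + rnorm(1, 0, spec$baseline_sd)
    sig <- rep(base, n)
    if (spec$drift_sd > 0) sig <- sig + cumsum(rnorm(n, 0, spec$drift_sd))

    q <- estimates$state_change_probability
    h <- estimates$state_entropy
    amp <- spec$b_feedback * as.numeric(session$reward < 0) +
      spec$b_changeprob * ifelse(is.na(q), 0, q) +
      spec$b_entropy * ifelse(is.na(h), 0, h)
    for (i in seq_len(nrow(session))) {
      onset <- session$feedback_onset_s[i]
      i0 <- max(1L, floor(onset * fs) + 2L)
      i1 <- min(n, ceiling((onset + 8) * fs))
      if (i1 < i0) next
      use <- i0:i1
      sig[use] <- sig[use] + amp[i] *
        .pupil_kernel(tt[use] - onset, spec$kernel_shape, spec$kernel_scale)
    }

    innov <- rnorm(n, 0, spec$ar_sd)
    ar <- as.numeric(stats::filter(innov, spec$ar_coef,
                                   method = "recursive"))
    sig <- sig + ar

    left <- sig + rnorm(n, 0, spec$eye_sd)
    right <- sig + rnorm(n, 0, spec$eye_sd)

    lblink <- rblink <- rep(FALSE, n)
    n_blinks <- stats::rpois(1, spec$blink_rate * t_end)
    if (n_blinks > 0) {
      starts <- runif(n_blinks, 0, t_end)
      durs <- runif(n_blinks, spec$blink_dur_range[1],
                    spec$blink_dur_range[2])
      which_eye <- runif(n_blinks) # < 0.9: both eyes
      for (b in seq_len(n_blinks)) {
        i0 <- max(1L, ceiling(starts[b] * fs) + 1L)
        i1 <- min(n, floor((starts[b] + durs[b]) * fs) + 1L)
        if (i1 < i0) next
        span <- i0:i1
        if (which_eye[b] < 0.95) lblink[span] <- TRUE
        if (which_eye[b] < 0.90 || which_eye[b] >= 0.95) rblink[span] <- TRUE
      }
    }
    left[lblink] <- NA_real_
    right[rblink] <- NA_real_

    samples <- data.frame(time_s = tt, left_mm = left, right_mm = right,
                          left_blink = lblink, right_blink = rblink)
    events <- data.frame(trial = session$trial,
                         feedback_onset_s = session$feedback_onset_s,
                         feedback_sign = ifelse(session$reward >= 0, 1L, -1L))
    structure(list(samples = samples, events = events, baseline_mm = base,
                   sample_rate = fs),
              class = "raw_pupil_recording")
  })
}

#' Inject isolated artifact spikes into a recording
#'
#' Adds spikes of a given magnitude (in SD units of the eye-averaged series)
#' at random positions outside blink gaps, for exercising the outlier-removal
#' rule. Returns the spiked recording and the sample indices hit.
#'
#' @param recording a `raw_pupil_recording`.
#' @param n_spikes number of spikes.
#' @param magnitude_sd spike height in SDs of the series (must exceed 3 to be
#'   detectable by the 3 SD rule).
#' @param seed RNG seed.
#' @return list: `recording` (modified), `positions` (sample indices).
#' @export
inject_artifacts <- function(recording, n_spikes, magnitude_sd = 6,
                             seed = 1L) {
  if (n_spikes == 0) {
    return(list(recording = recording, positions = integer()))
  }
  s <- recording$samples
  free <- which(!s$left_blink & !s$right_blink &
                  !is.na(s$left_mm) & !is.na(s$right_mm))
  if (length(free) < n_spikes) stop("more spikes than free samples")
  with_seed(seed, {
    pos <- sort(sample(free, n_spikes))
    avg <- (s$left_mm + s$right_mm) / 2
    mag <- magnitude_sd * sd(avg, na.rm = TRUE) *
      sample(c(-1, 1), n_spikes, replace = TRUE)
    s$left_mm[pos] <- s$left_mm[pos] + mag
    s$right_mm[pos] <- s$right_mm[pos] + mag
    recording$samples <- s
    list(recording = recording, positions = pos)
  })
}
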