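#' Clean a raw two-eye pupil recording to a 50 Hz series
#'
#' Applies the preprocessing chain in order: average the two eyes; delete
#' samples flagged as blink in at least one eye; delete samples deviating from
#' the series mean by more than 3 SDs, plus 10 samples (40 ms) of padding on
#' each side of every such segment; resample to 50 Hz by missing-aware means
#' of non-overlapping 5-sample blocks; linearly interpolate remaining gaps
#' (edge gaps by nearest-value extension); smooth with a Savitzky-Golay
#' filter (frame 9, order 4). The outlier rule runs before resampling because
#' its padding is specified in 250 Hz samples.
#'
#' @param recording a `raw_pupil_recording` (see [generate_recording()]) or a
#'   compatible list with `samples` and `sample_rate`.
#' @param out_rate output rate, default 50 Hz.
#' @param sd_cut outlier threshold in SDs (default 3).
#' @param pad_samples padding around deleted outlier segments, in input
#'   samples (default 10).
#' @return list of class `clean_pupil_series`: `time_s`, `value_mm` (both at
#'   `out_rate`), `interpolated` (logical per output bin), and
#'   `interpolated_pct`.
#' @export
clean_series <- function(recording, out_rate = 50, sd_cut = 3,
                         pad_samples = 10L) {
  s <- recording$samples
  fs <- recording$sample_rate
  block <- fs / out_rate
  if (abs(block - round(block)) > 1e-9) {
    stop("input rate must be an integer multiple of `out_rate`")
  }
  block <- as.integer(round(block))

  v <- rowMeans(cbind(s$left_mm, s$right_mm), na.rm = TRUE)
  v[is.nan(v)] <- NA_real_
  v[s$left_blink | s$right_blink] <- NA_real_
  if (all(is.na(v))) stop("series entirely missing after blink removal")

  mu <- mean(v, na.rm = TRUE)
  sdev <- sd(v, na.rm = TRUE)
  if (is.finite(sdev) && sdev > 0) {
    bad <- which(!is.na(v) & abs(v - mu) > sd_cut * sdev)
    if (length(bad) > 0) {
      pad <- unique(unlist(lapply(bad, function(i) {
        seq(max(1L, i - pad_samples), min(length(v), i + pad_samples))
      })))
      v[pad] <- NA_real_
    }
  }

  nb <- floor(length(v) / block)
  vm <- matrix(v[seq_len(nb * block)], nrow = block)
  vv <- colMeans(vm, na.rm = TRUE)
  vv[is.nan(vv)] <- NA_real_
  # stamp each block with its center time so values stay phase-aligned
  t50 <- colMeans(matrix(s$time_s[seq_len(nb * block)], nrow = block))

  gap <- is.na(vv)
  if (all(gap)) stop("series entirely missing")
  if (any(gap)) {
    vv <- approx(t50[!gap], vv[!gap], xout = t50, method = "linear",
                 rule = 2)$y
  }
  vv <- sgolay_filter(vv, 9L, 4L)

  structure(list(time_s = t50, value_mm = vv, interpolated = gap,
                 interpolated_pct = 100 * mean(gap), out_rate = out_rate),
            class = "clean_pupil_series")
}

#' Extract baseline-corrected feedback-locked epochs
#'
#' Cuts the cleaned 50 Hz series into one epoch per retained trial, spanning
#' -1 s to +6 s around feedback onset on a half-open `[-1, 6)` grid of
#' exactly 350 bins (feedback onset at bin index 51). The mean of the 500 ms
#' (25 bins) preceding feedback is stored as `baseline` and subtracted from
#' every bin. The first five trials and the last trial are dropped, matching
#' the statistical protocol; exclusion reasons are reported.
#'
#' @param cleaned a `clean_pupil_series`.
#' @param events events data frame with `trial` and `feedback_onset_s`
#'   (e.g. `recording$events`).
#' @param drop_first number of initial trials to drop (default 5).
#' @param drop_last number of final trials to drop (default 1).
#' @return list of class `pupil_epochs`: `epochs` long data frame (`trial`,
#'   `bin` 1..350, `time_s` relative to feedback, `value`, `baseline`),
#'   `dropped` data frame of excluded trials with reasons, `bin_times`.
#' @export
epoch_and_baseline <- function(cleaned, events, drop_first = 5L,
                               drop_last = 1L) {
  fs <- cleaned$out_rate
  n_bins <- as.integer(7 * fs) # [-1, 6) at 50 Hz: 350 bins
  rel <- (seq_len(n_bins) - 1) / fs - 1
  base_bins <- which(rel >= -0.5 & rel < 0)
  t0 <- cleaned$time_s[1]
  dt <- 1 / fs

  keep <- events
  dropped <- data.frame(trial = integer(), reason = character())
  nt <- nrow(events)
  drop_idx <- c(seq_len(min(drop_first, nt)),
                if (drop_last > 0) seq(nt - drop_last + 1L, nt))
  drop_idx <- unique(drop_idx[drop_idx >= 1 & drop_idx <= nt])
  if (length(drop_idx)) {
    dropped <- data.frame(trial = events$trial[drop_idx],
                          reason = ifelse(drop_idx <= drop_first,
                                          "first_trials", "last_trial"))
    keep <- events[-drop_idx, , drop = FALSE]
  }

  out <- vector("list", nrow(keep))
  for (i in seq_len(nrow(keep))) {
    onset <- keep$feedback_onset_s[i]
    idx0 <- round((onset - 1 - t0) / dt) + 1
    idx <- idx0 + seq_len(n_bins) - 1
    if (idx0 < 1 || max(idx) > length(cleaned$value_mm)) {
      stop(sprintf("epoch window for trial %d exceeds the recording span",
                   keep$trial[i]))
    }
    vals <- cleaned$value_mm[idx]
    bl <- mean(vals[base_bins])
    out[[i]] <- data.frame(trial = keep$trial[i], bin = seq_len(n_bins),
                           time_s = rel, value = vals - bl, baseline = bl)
  }
  structure(list(epochs = do.call(rbind, out), dropped = dropped,
                 bin_times = rel, n_bins = n_bins),
            class = "pupil_epochs")
}

#' Flag participants with excessive interpolation
#'
#' Participants whose interpolated-sample percentage exceeds the cohort mean
#' by more than 2.5 SD are flagged for exclusion from pupil analyses only
#' (behavioral and model-fit analyses keep them).
#'
#' @param interpolated_pct numeric vector of per-participant interpolated
#'   percentages (e.g. from [clean_series()] reports).
#' @param sd_cut threshold in cohort SDs (default 2.5).
#' @return logical vector of exclusion flags.
#' @export
#' @examples
#' participant_exclusion(c(5, 6, 5.5, 20))
participant_exclusion <- function(interpolated_pct, sd_cut = 2.5) {
  if (length(interpolated_pct) < 2) stop("need at least two participants")
  mu <- mean(interpolated_pct)
  sdev <- sd(interpolated_pct)
  if (!is.finite(sdev) || sdev == 0) {
    return(rep(FALSE, length(interpolated_pct)))
  }
  interpolated_pct > mu + sd_cut * sdev
}
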