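# Plain-text readers/writers for the pipeline's tabular interfaces.

#' Write / read a session table as TSV
#'
#' One row per trial with columns `trial, z, x, y, reward, reversal,
#' feedback_onset_s, score`.
#'
#' @param session a `session_record`.
#' @param path file path.
#' @return `read_session_tsv` returns a `session_record`.
#' @export
write_session_tsv <- function(session, path) {
  write.table(session, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_tsv
#' @export
read_session_tsv <- function(path) {
  out <- read.delim(path)
  out$reversal <- as.logical(out$reversal)
  class(out) <- c("session_record", "data.frame")
  out
}

#' Write trial estimates as TSV
#'
#' @param estimates a `trial_estimates` data frame from [run_filter()].
#' @param path file path.
#' @export
write_estimates_tsv <- function(estimates, path) {
  write.table(estimates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_estimates_tsv
#' @export
read_estimates_tsv <- function(path) {
  out <- read.delim(path)
  class(out) <- c("trial_estimates", "data.frame")
  out
}

#' Write / read a raw pupil recording (samples + events TSVs)
#'
#' @param recording a `raw_pupil_recording`.
#' @param samples_path,events_path file paths.
#' @export
write_recording_tsv <- function(recording, samples_path, events_path) {
  write.table(recording$samples, samples_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(recording$events, events_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(samples_path)
}

#' @rdname write_recording_tsv
#' @param sample_rate sampling rate of the stored stream (Hz).
#' @export
read_recording_tsv <- function(samples_path, events_path,
                               sample_rate = 250) {
  samples <- read.delim(samples_path)
  samples$left_blink <- as.logical(samples$left_blink)
  samples$right_blink <- as.logical(samples$right_blink)
  structure(list(samples = samples, events = read.delim(events_path),
                 sample_rate = sample_rate),
            class = "raw_pupil_recording")
}
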