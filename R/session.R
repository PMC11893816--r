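# Core containers: continuous sessions and epoched trial sets.

#' Construct a continuous EEG session
#'
#' @param signal Numeric matrix, channels x samples, microvolts. Row order
#'   must follow `montage$channel`.
#' @param fs Sampling rate in Hz (> 0).
#' @param events Tibble/data.frame with integer columns `sample` (0-based
#'   index into the signal) and `code`.
#' @param montage A [montage_1010()] object with one row per signal row.
#' @param subject_id,session_id Character identifiers.
#' @param event_codes Named list documenting the code mapping (e.g.
#'   `list(left = 1, right = 2)`).
#' @return An object of class `raw_session`.
#' @export
raw_session <- function(signal, fs, events, montage, subject_id = "S01",
                        session_id = "T", event_codes = NULL) {
  signal <- as.matrix(signal)
  assert_that(is.numeric(fs) && length(fs) == 1 && fs > 0, "fs must be a positive scalar")
  assert_that(all(is.finite(signal)), "signal must be finite")
  assert_that(is_montage(montage), "montage must be a montage object")
  assert_that(nrow(signal) == nrow(montage),
              sprintf("signal has %d rows but montage %d channels", nrow(signal), nrow(montage)))
  events <- tibble::as_tibble(events)
  assert_that(all(c("sample", "code") %in% names(events)), "events need columns sample, code")
  assert_that(all(events$sample >= 0 & events$sample < ncol(signal)),
              "event sample indices must lie within the signal")
  rownames(signal) <- montage$channel
  structure(
    list(signal = signal, fs = fs, events = events, montage = montage,
         subject_id = subject_id, session_id = session_id,
         event_codes = event_codes),
    class = "raw_session"
  )
}

#' @export
print.raw_session <- function(x, ...) {
  cat(sprintf("<raw_session> %s/%s: %d ch x %d samples @ %g Hz, %d events\n",
              x$subject_id, x$session_id, nrow(x$signal), ncol(x$signal),
              x$fs, nrow(x$events)))
  invisible(x)
}

#' Construct an epoched trial set
#'
#' @param data Numeric array trials x channels x samples.
#' @param labels Integer class labels in `0 .. n_classes-1`, one per trial.
#' @param channels Character channel labels (length = dim 2 of `data`).
#' @param fs_effective Sampling rate after subsampling, Hz.
#' @param window_start_s,window_len_s Sample-window position in seconds
#'   relative to trial onset; windows are half-open `[start, start+len)`.
#' @param subsample_n 1:n subsampling factor already applied (>= 1).
#' @param n_classes Number of classes (default `max(labels) + 1`).
#' @param montage Optional montage carrying grid coordinates.
#' @return An object of class `epoched_dataset`.
#' @export
epoched_dataset <- function(data, labels, channels, fs_effective,
                            window_start_s = 2, window_len_s = 4,
                            subsample_n = 1L, n_classes = NULL, montage = NULL) {
  assert_that(length(dim(data)) == 3, "data must be trials x channels x samples")
  labels <- as.integer(labels)
  assert_that(dim(data)[1] == length(labels),
              "labels length must equal the number of trials")
  assert_that(dim(data)[2] == length(channels),
              "channels length must match data dim 2")
  n_classes <- as.integer(n_classes %||% (max(labels) + 1L))
  assert_that(all(labels >= 0 & labels < n_classes),
              "labels must lie in 0 .. n_classes-1")
  assert_that(is_count(subsample_n), "subsample_n must be a positive integer")
  structure(
    list(data = data, labels = labels, channels = as.character(channels),
         fs_effective = fs_effective, window_start_s = window_start_s,
         window_len_s = window_len_s, subsample_n = as.integer(subsample_n),
         n_classes = n_classes, montage = montage),
    class = "epoched_dataset"
  )
}

#' @export
print.epoched_dataset <- function(x, ...) {
  cat(sprintf("<epoched_dataset> %d trials x %d ch x %d samples @ %g Hz (%d classes, window %.2g+%.2g s, 1:%d)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs_effective,
              x$n_classes, x$window_start_s, x$window_len_s, x$subsample_n))
  invisible(x)
}

n_trials <- function(ep) dim(ep$data)[1]

#' Select trials from an epoched dataset
#'
#' @param ep An [epoched_dataset()].
#' @param idx Trial indices (1-based).
#' @return An `epoched_dataset` with the selected trials.
#' @export
epochs_subset <- function(ep, idx) {
  out <- ep
  out$data <- ep$data[idx, , , drop = FALSE]
  out$labels <- ep$labels[idx]
  out
}

#' Select channels from an epoched dataset
#'
#' @param ep An [epoched_dataset()].
#' @param channels Channel labels to keep.
#' @return An `epoched_dataset` restricted to `channels`.
#' @export
epochs_select_channels <- function(ep, channels) {
  j <- match(toupper(channels), toupper(ep$channels))
  assert_that(!anyNA(j), paste0("channel(s) not present: ",
                                paste(channels[is.na(j)], collapse = ", ")))
  out <- ep
  out$data <- ep$data[, j, , drop = FALSE]
  out$channels <- ep$channels[j]
  if (!is.null(ep$montage)) out$montage <- montage_subset(ep$montage, out$channels)
  out
}
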