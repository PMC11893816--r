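# Preprocessing chain: band-pass + notch filtering, cue-locked epoching,
# 1:n subsampling, and per-channel standardization with train-set
# statistics. Pipeline order is filter -> epoch -> subsample -> standardize.

#' Preprocessing specification
#'
#' @param bandpass_hz Band-pass corner frequencies, Hz (4th-order
#'   Butterworth, applied forward-backward for zero phase).
#' @param notch_hz Band-stop edges, Hz (2nd-order Butterworth, zero phase).
#' @param window_start_s Sample-window start relative to trial onset (s).
#' @param window_len_s Sample-window length (s).
#' @param subsample_n 1:n subsampling factor (plain decimation, n >= 1).
#' @return A list of class `preprocess_spec`.
#' @export
preprocess_spec <- function(bandpass_hz = c(0.5, 60), notch_hz = c(48, 52),
                            window_start_s = 2, window_len_s = 4,
                            subsample_n = 1L) {
  assert_that(length(bandpass_hz) == 2 && bandpass_hz[1] > 0 &&
                bandpass_hz[1] < bandpass_hz[2],
              "bandpass_hz must satisfy 0 < low < high")
  assert_that(is_count(subsample_n), "subsample_n must be a positive integer")
  assert_that(window_len_s > 0, "window_len_s must be positive")
  structure(list(bandpass_hz = bandpass_hz, notch_hz = notch_hz,
                 window_start_s = window_start_s, window_len_s = window_len_s,
                 subsample_n = as.integer(subsample_n)),
            class = "preprocess_spec")
}

#' Band-pass and notch filter a session
#'
#' Applies the spec's Butterworth band-pass (order 4) followed by the
#' band-stop notch (order 2), each per channel and forward-backward
#' (zero-phase); signal length is preserved.
#'
#' @param raw A [raw_session()].
#' @param spec A [preprocess_spec()].
#' @return The filtered [raw_session()].
#' @export
filter_session <- function(raw, spec = preprocess_spec()) {
  stopifnot(inherits(raw, "raw_session"))
  nyq <- raw$fs / 2
  if (spec$bandpass_hz[2] >= nyq || (!is.null(spec$notch_hz) && spec$notch_hz[2] >= nyq))
    stop("configuration error: filter band edges must be below the Nyquist ",
         "frequency (", nyq, " Hz)", call. = FALSE)
  bp <- signal::butter(4, spec$bandpass_hz / nyq, type = "pass")
  bs <- if (!is.null(spec$notch_hz)) signal::butter(2, spec$notch_hz / nyq, type = "stop")
  for (ch in seq_len(nrow(raw$signal))) {
    x <- signal::filtfilt(bp, raw$signal[ch, ])
    if (!is.null(bs)) x <- signal::filtfilt(bs, x)
    raw$signal[ch, ] <- x
  }
  raw
}

#' Extract cue-locked epochs
#'
#' Cuts one sample window per trial from the half-open interval
#' `[onset + window_start_s, onset + window_start_s + window_len_s)`;
#' at 250 Hz a 4 s window yields 1000 samples.
#'
#' @param raw A [raw_session()].
#' @param spec A [preprocess_spec()].
#' @param onsets Optional integer vector of onset samples (0-based);
#'   defaults to all session events. Labels are taken as `code - 1`.
#' @return An [epoched_dataset()] (subsample_n = 1; apply [subsample()]
#'   afterwards).
#' @export
epoch <- function(raw, spec = preprocess_spec(), onsets = NULL) {
  stopifnot(inherits(raw, "raw_session"))
  ev <- raw$events
  if (!is.null(onsets)) ev <- ev[ev$sample %in% onsets, ]
  n_samp <- floor(spec$window_len_s * raw$fs)
  first <- ev$sample + floor(spec$window_start_s * raw$fs)   # 0-based
  bad <- which(first + n_samp > ncol(raw$signal) | first < 0)
  if (length(bad) > 0)
    stop("window overruns the recording for trial(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  n_tr <- nrow(ev)
  data <- array(0, c(n_tr, nrow(raw$signal), n_samp))
  for (t in seq_len(n_tr))
    data[t, , ] <- raw$signal[, (first[t] + 1):(first[t] + n_samp), drop = FALSE]
  epoched_dataset(data, labels = ev$code - 1L, channels = raw$montage$channel,
                  fs_effective = raw$fs, window_start_s = spec$window_start_s,
                  window_len_s = spec$window_len_s, subsample_n = 1L,
                  montage = raw$montage)
}

#' 1:n subsampling (plain decimation)
#'
#' Keeps samples at indices 0, n, 2n, ... of each epoch (so `ceiling(L/n)`
#' samples remain) and divides the effective sampling rate by `n`. No
#' anti-alias prefilter is applied: the 60 Hz band-pass limits aliasing for
#' n <= 2, and for larger n the aliasing is an accepted part of the
#' measurement-condition tradeoff under study.
#'
#' @param ep An [epoched_dataset()].
#' @param n Subsampling factor (integer >= 1); `n = 1` is the identity.
#' @return The decimated [epoched_dataset()].
#' @export
subsample <- function(ep, n) {
  stopifnot(inherits(ep, "epoched_dataset"))
  if (!is_count(n)) stop("configuration error: subsample n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  if (n == 1L) return(ep)
  keep <- seq(1L, dim(ep$data)[3], by = n)
  ep$data <- ep$data[, , keep, drop = FALSE]
  ep$fs_effective <- ep$fs_effective / n
  ep$subsample_n <- ep$subsample_n * n
  ep
}

#' Standardize epochs with training-set statistics
#'
#' Computes the per-channel mean and population standard deviation
#' (divide-by-N) pooled over all training trials and time points, and
#' applies the same affine transform to the training set and to every
#' dataset in `others` (test/validation sets are never allowed to leak
#' into the statistics).
#'
#' @param train An [epoched_dataset()]; source of the statistics.
#' @param others List of further [epoched_dataset()]s to transform.
#' @return List with `stats` (tibble: channel, mean, sd), `train`, and
#'   `others` (transformed datasets).
#' @export
standardize <- function(train, others = list()) {
  stopifnot(inherits(train, "epoched_dataset"))
  if (inherits(others, "epoched_dataset")) others <- list(others)
  n_ch <- dim(train$data)[2]
  mu <- sig <- numeric(n_ch)
  for (ch in seq_len(n_ch)) {
    v <- as.numeric(train$data[, ch, ])
    mu[ch] <- mean(v)
    sig[ch] <- sqrt(mean((v - mu[ch])^2))    # population convention
  }
  zero <- which(sig == 0)
  if (length(zero) > 0)
    stop("zero-variance channel(s) in training set: ",
         paste(train$channels[zero], collapse = ", "), call. = FALSE)
  xf <- function(ep) {
    for (ch in seq_len(n_ch)) ep$data[, ch, ] <- (ep$data[, ch, ] - mu[ch]) / sig[ch]
    ep
  }
  list(stats = tibble::tibble(channel = train$channels, mean = mu, sd = sig),
       train = xf(train), others = lapply(others, xf))
}

#' Run the full preprocessing chain on a session
#'
#' filter -> epoch -> subsample; standardization is deferred to
#' train/test-aware callers (see [standardize()]).
#'
#' @param raw A [raw_session()].
#' @param spec A [preprocess_spec()].
#' @return An [epoched_dataset()].
#' @export
preprocess_session <- function(raw, spec = preprocess_spec()) {
  subsample(epoch(filter_session(raw, spec), spec), spec$subsample_n)
}
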