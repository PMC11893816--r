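# Event-related desynchronization / synchronization (ERD/ERS): per-channel
# band-power change of an analysis interval relative to a baseline
# interval, expressed in percent, and its placement on the scalp grid.

band_power_epochs <- function(raw, band, interval) {
  bf <- signal::butter(4, band / (raw$fs / 2), type = "pass")
  i0 <- floor(interval[1] * raw$fs)
  i1 <- floor(interval[2] * raw$fs)
  n_ch <- nrow(raw$signal)
  onsets <- raw$events$sample
  pw <- matrix(NA_real_, length(onsets), n_ch)
  for (ch in seq_len(n_ch)) {
    x <- signal::filtfilt(bf, raw$signal[ch, ])
    for (t in seq_along(onsets)) {
      a <- onsets[t] + i0 + 1L
      b <- min(onsets[t] + i1, length(x))
      pw[t, ch] <- mean(x[a:b]^2)
    }
  }
  pw
}

#' Per-channel ERD/ERS percentage
#'
#' For each channel, `ERD% = (A - R) / R * 100` where `A` is the
#' trial-averaged band power in the analysis interval and `R` in the
#' baseline interval (band power = mean squared amplitude after zero-phase
#' band-pass filtering). Negative values are desynchronization; the lower
#' bound is -100 because power cannot be negative. A noise-free
#' oscillation whose amplitude is scaled by `a` during the analysis
#' interval yields `(a^2 - 1) * 100`.
#'
#' @param raw A [raw_session()] whose events mark trial onsets; pass
#'   `classes` to restrict to one condition.
#' @param band Band edges in Hz (default mu, 8-12).
#' @param baseline Baseline interval in seconds relative to trial onset
#'   (default the 0-2 s fixation segment), half-open.
#' @param analysis Analysis interval in seconds relative to trial onset
#'   (default the 3.25-7.25 s motor-imagery segment).
#' @param classes Optional event codes to keep (e.g. `1` for the first
#'   class when codes are `class + 1`).
#' @return A tibble of class `erd_map`: columns `channel`, `erd_pct`,
#'   `baseline_power`, `analysis_power`; band and intervals kept as
#'   attributes. Channels with zero baseline power get `NA` with a warning.
#' @export
erd_percent <- function(raw, band = c(8, 12), baseline = c(0, 2),
                        analysis = c(3.25, 7.25), classes = NULL) {
  stopifnot(inherits(raw, "raw_session"))
  assert_that(band[1] > 0 && band[2] < raw$fs / 2,
              "band must lie inside (0, fs/2)")
  assert_that(baseline[1] < baseline[2] && analysis[1] < analysis[2],
              "intervals must be increasing")
  if (!is.null(classes)) {
    keep <- raw$events$code %in% classes
    assert_that(any(keep), "no events with the requested class codes")
    raw$events <- raw$events[keep, ]
  }
  R <- colMeans(band_power_epochs(raw, band, baseline))
  A <- colMeans(band_power_epochs(raw, band, analysis))
  erd <- ifelse(R > 0, (A - R) / R * 100, NA_real_)
  if (anyNA(erd))
    warning("zero baseline power; ERD undefined for channel(s): ",
            paste(raw$montage$channel[is.na(erd)], collapse = ", "))
  out <- tibble::tibble(channel = raw$montage$channel, erd_pct = erd,
                        baseline_power = R, analysis_power = A)
  structure(out, class = c("erd_map", class(out)),
            band = band, baseline = baseline, analysis = analysis,
            montage = raw$montage)
}

#' Place an ERD map on a scalp grid
#'
#' @param map An [erd_percent()] result.
#' @param layout A [grid_layout()] containing every map channel.
#' @return A `C1 x C2` numeric matrix with ERD percent at electrode cells
#'   and `NA` at cells without an electrode (absent, as opposed to an ERD
#'   of zero).
#' @export
grid_topomap <- function(map, layout) {
  stopifnot(inherits(map, "erd_map"), inherits(layout, "grid_layout"))
  pos <- match(toupper(map$channel), toupper(layout$cell_map$channel))
  if (anyNA(pos))
    stop("channel(s) not in layout: ",
         paste(map$channel[is.na(pos)], collapse = ", "), call. = FALSE)
  g <- matrix(NA_real_, layout$c1, layout$c2)
  for (j in seq_along(pos))
    g[layout$cell_map$row[pos[j]] + 1L, layout$cell_map$col[pos[j]] + 1L] <-
      map$erd_pct[j]
  g
}
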