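# Synthetic motor-imagery EEG: 1/f background plus band-limited mu/beta
# oscillations whose amplitude is attenuated (ERD) during each trial's
# motor-imagery interval, lateralized by class.

#' Default class-to-channel ERD attenuation profile
#'
#' Encodes the contralateral organisation of motor-imagery ERD: imagining
#' the left hand attenuates oscillations over the right-hemisphere motor
#' strip (C4 side) and vice versa, feet attenuate the midline, and tongue
#' attenuates both hemispheres with a shallower depth. Attenuation factors
#' multiply oscillation amplitude, so a factor `a` yields a band-power
#' change of `(a^2 - 1) * 100` percent in the noise-free limit.
#'
#' @param montage A [montage_1010()] object.
#' @param n_classes 2 (left/right hand) or 4 (left, right, feet, tongue).
#' @param depth Amplitude attenuation factor in (0, 1] applied to the
#'   targeted channels.
#' @param bilateral_scale Fraction of the depth applied for the tongue
#'   class (shallower, bilateral).
#' @return Matrix `n_classes x n_channels` of amplitude factors.
#' @export
erd_profile <- function(montage, n_classes = 4, depth = 0.6, bilateral_scale = 0.5) {
  assert_that(n_classes %in% c(2L, 4L), "n_classes must be 2 or 4")
  assert_that(depth > 0 && depth <= 1, "depth must lie in (0, 1]")
  side <- montage_side(montage)
  motor_row <- montage$row %in% 1:3         # FC/C/CP strip
  left  <- side < 0 & motor_row
  right <- side > 0 & motor_row
  mid   <- side == 0 & montage$row %in% 1:4
  if (!any(left) || !any(right))
    stop("configuration error: montage lacks left/right motor channels ",
         "needed for lateralized classes", call. = FALSE)
  fac <- matrix(1, nrow = n_classes, ncol = nrow(montage),
                dimnames = list(NULL, montage$channel))
  fac[1, right] <- depth                    # left hand -> contralateral (right) ERD
  fac[2, left] <- depth                     # right hand -> left ERD
  if (n_classes == 4) {
    fac[3, mid] <- depth                    # feet -> midline
    shallow <- 1 - (1 - depth) * bilateral_scale
    fac[4, left | right] <- shallow         # tongue -> bilateral, shallower
  }
  fac
}

#' Simulation configuration
#'
#' The defaults emulate a 250 Hz motor-imagery acquisition with the timing
#' paradigm fixation 2 s, cue 1.25 s, motor imagery 4 s, break 2 s. Each
#' channel carries spectrally shaped 1/f background noise (independent per
#' channel plus a common source for spatial correlation), white sensor
#' noise, and band-limited mu (8-12 Hz) and beta (18-26 Hz) oscillations.
#' During the ERD interval of each trial the oscillation amplitude is
#' multiplied by the class/channel attenuation factor, entered and left via
#' a raised-cosine ramp to avoid spectral splatter.
#'
#' @param n_trials_per_class Trials per class.
#' @param n_classes 2 or 4.
#' @param montage A [montage_1010()] object.
#' @param fs Sampling rate, Hz.
#' @param paradigm Named list of segment durations in seconds:
#'   `fixation_s`, `cue_s`, `mi_s`, `break_s`.
#' @param erd_depth `n_classes x n_channels` matrix of amplitude attenuation
#'   factors in (0, 1], or `NULL` to use [erd_profile()] with `depth`.
#' @param depth Depth handed to [erd_profile()] when `erd_depth` is `NULL`.
#' @param osc_bands List of `c(low_hz, high_hz, amplitude)` oscillation bands.
#' @param noise List with `one_over_f_exponent` (spectral slope of the
#'   background), `pink_sd` (its standard deviation), `white_sd` (additive
#'   white noise SD) and `common_sd` (shared-source background, simulating
#'   spatial correlation).
#' @param erd_start_s Start of the ERD interval relative to trial onset;
#'   defaults to `fixation_s + cue_s` (the motor-imagery segment).
#' @param erd_dur_s Duration of the ERD interval; defaults to `mi_s`.
#' @param erd_ramp_s Raised-cosine ramp length at both interval edges.
#' @param seed Integer seed; identical configurations produce bit-identical
#'   sessions.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_trials_per_class = 72, n_classes = 4,
                       montage = montage_22(), fs = 250,
                       paradigm = list(fixation_s = 2, cue_s = 1.25,
                                       mi_s = 4, break_s = 2),
                       erd_depth = NULL, depth = 0.6,
                       osc_bands = list(c(8, 12, 1.0), c(18, 26, 0.5)),
                       noise = list(one_over_f_exponent = 1, pink_sd = 1,
                                    white_sd = 0.3, common_sd = 0.3),
                       erd_start_s = NULL, erd_dur_s = NULL,
                       erd_ramp_s = 0.25, seed = 1L) {
  assert_that(is_count(n_trials_per_class), "n_trials_per_class must be a count")
  assert_that(n_classes %in% c(2L, 4L), "n_classes must be 2 or 4")
  assert_that(all(unlist(paradigm) > 0), "paradigm durations must be positive")
  hi <- max(vapply(osc_bands, function(b) b[2], 0))
  assert_that(fs > 2 * hi, "fs must exceed twice the highest band edge")
  if (is.null(erd_depth)) erd_depth <- erd_profile(montage, n_classes, depth = depth)
  assert_that(all(erd_depth > 0 & erd_depth <= 1),
              "attenuation factors must lie in (0, 1]")
  assert_that(identical(dim(erd_depth), c(as.integer(n_classes), nrow(montage))) ||
                identical(dim(erd_depth), c(n_classes, nrow(montage))),
              "erd_depth must be n_classes x n_channels")
  structure(
    list(n_trials_per_class = as.integer(n_trials_per_class),
         n_classes = as.integer(n_classes), montage = montage, fs = fs,
         paradigm = paradigm, erd_depth = erd_depth, osc_bands = osc_bands,
         noise = noise,
         erd_start_s = erd_start_s %||% (paradigm$fixation_s + paradigm$cue_s),
         erd_dur_s = erd_dur_s %||% paradigm$mi_s,
         erd_ramp_s = erd_ramp_s, seed = as.integer(seed)),
    class = "sim_config")
}

# 1/f^alpha noise by spectral shaping of white noise
colored_noise <- function(n, alpha, sd_target) {
  if (sd_target <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  if (alpha == 0) return(w * sd_target / stats::sd(w))
  f <- stats::fft(w)
  k <- c(1, seq_len(n - 1))                 # keep DC unscaled at index 1
  freq <- pmin(k, n - k + 1)                # symmetric frequency index
  shape <- freq^(-alpha / 2)
  shape[1] <- 0                             # drop DC
  x <- Re(stats::fft(f * shape, inverse = TRUE)) / n
  x * sd_target / stats::sd(x)
}

narrowband_osc <- function(n, band, amp, fs) {
  if (amp <= 0) return(numeric(n))
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x * amp / stats::sd(x)
}

# per-trial amplitude gain with raised-cosine edges; modifies `gain` in place
apply_erd_gain <- function(gain, onset, a, start_samp, dur_samp, ramp_samp) {
  if (a == 1) return(gain)
  i0 <- onset + start_samp + 1L             # 1-based
  i1 <- min(onset + start_samp + dur_samp, length(gain))
  if (i1 < i0) return(gain)
  seg <- rep(a, i1 - i0 + 1L)
  nr <- min(ramp_samp, floor(length(seg) / 2))
  if (nr > 0) {
    w <- (1 + cos(pi * seq_len(nr) / nr)) / 2         # ~1 -> 0
    down <- a + (1 - a) * w                           # 1 -> a
    seg[seq_len(nr)] <- down
    seg[(length(seg) - nr + 1):length(seg)] <- rev(down)
  }
  gain[i0:i1] <- seg
  gain
}

#' Simulate a continuous motor-imagery session
#'
#' Generates a seeded [raw_session()] following the configured timing
#' paradigm, together with the ground truth needed for parameter-recovery
#' tests. One event per trial marks the trial onset; its code is
#' `class + 1` (mapping declared in `event_codes`).
#'
#' @param config A [sim_config()].
#' @return List with elements `session` ([raw_session()]) and `truth`
#'   (tibble of trial, onset sample and class, plus the applied per-trial,
#'   per-channel ERD factors as attribute `"erd_factors"`).
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fs <- config$fs
  mont <- config$montage
  n_ch <- nrow(mont)
  K <- config$n_classes
  n_tr <- config$n_trials_per_class * K

  seg <- with(config$paradigm, c(fixation_s, cue_s, mi_s, break_s))
  trial_len <- floor(sum(seg) * fs)
  N <- n_tr * trial_len
  onsets <- (seq_len(n_tr) - 1L) * trial_len

  classes <- sample(rep.int(0:(K - 1L), config$n_trials_per_class))
  start_samp <- floor(config$erd_start_s * fs)
  dur_samp <- floor(config$erd_dur_s * fs)
  ramp_samp <- floor(config$erd_ramp_s * fs)

  common <- colored_noise(N, config$noise$one_over_f_exponent,
                          config$noise$common_sd %||% 0)
  signal <- matrix(0, n_ch, N)
  erd_factors <- matrix(1, n_tr, n_ch, dimnames = list(NULL, mont$channel))
  for (ch in seq_len(n_ch)) {
    bg <- colored_noise(N, config$noise$one_over_f_exponent, config$noise$pink_sd) +
      common
    if (config$noise$white_sd > 0) bg <- bg + stats::rnorm(N, sd = config$noise$white_sd)
    osc <- numeric(N)
    for (b in config$osc_bands) osc <- osc + narrowband_osc(N, b[1:2], b[3], fs)
    gain <- rep(1, N)
    for (t in seq_len(n_tr)) {
      a <- config$erd_depth[classes[t] + 1L, ch]
      erd_factors[t, ch] <- a
      gain <- apply_erd_gain(gain, onsets[t], a, start_samp, dur_samp, ramp_samp)
    }
    signal[ch, ] <- bg + osc * gain
  }

  class_names <- c("left", "right", "feet", "tongue")[seq_len(K)]
  sess <- raw_session(
    signal, fs = fs,
    events = tibble::tibble(sample = as.integer(onsets), code = classes + 1L),
    montage = mont, subject_id = sprintf("sim%02d", config$seed %% 100L),
    session_id = "sim",
    event_codes = as.list(stats::setNames(seq_len(K), class_names)))
  truth <- tibble::tibble(trial = seq_len(n_tr), onset_sample = as.integer(onsets),
                          class = classes)
  attr(truth, "erd_factors") <- erd_factors
  list(session = sess, truth = truth)
}

#' Generate benchmark-shaped synthetic train/test splits
#'
#' `"iv2a_like"` mimics a 22-channel, 4-class, two-session layout with 288
#' trials per session (72 per class); `"iv2b_like"` a 3-channel, 2-class
#' layout with 400 training and 320 test trials. Train and test sessions
#' are generated from independent seeds derived from `seed` and epoched
#' with the standard cue-locked window (start 2 s, length 4 s, no
#' subsampling).
#'
#' @param seed Integer seed.
#' @param flavor `"iv2a_like"` or `"iv2b_like"`.
#' @param depth ERD amplitude attenuation passed to [erd_profile()].
#' @param noise Optional noise list overriding the [sim_config()] default.
#' @return List with `train` and `test` [epoched_dataset()]s.
#' @export
make_benchmark_like <- function(seed, flavor = c("iv2a_like", "iv2b_like"),
                                depth = 0.6, noise = NULL) {
  flavor <- match.arg(flavor)
  spec <- preprocess_spec(window_len_s = 4, subsample_n = 1L)
  gen <- function(n_per, k, mont, s) {
    args <- list(n_trials_per_class = n_per, n_classes = k, montage = mont,
                 depth = depth, seed = s)
    if (!is.null(noise)) args$noise <- noise
    sim <- simulate_session(do.call(sim_config, args))
    epoch(sim$session, spec)
  }
  if (flavor == "iv2a_like") {
    mont <- montage_22()
    list(train = gen(72L, 4L, mont, derive_seed(seed, "iv2a-train")),
         test  = gen(72L, 4L, mont, derive_seed(seed, "iv2a-test")))
  } else {
    mont <- montage_iv2b()
    list(train = gen(200L, 2L, mont, derive_seed(seed, "iv2b-train")),
         test  = gen(160L, 2L, mont, derive_seed(seed, "iv2b-test")))
  }
}
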