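# Filtering, epoching, decimation, standardization.

make_tone_session <- function(freqs, amps, fs = 250, dur = 20) {
  t <- seq_len(fs * dur) / fs
  x <- rowSums(vapply(seq_along(freqs),
                      function(i) amps[i] * sin(2 * pi * freqs[i] * t),
                      numeric(length(t))))
  raw_session(matrix(rep(x, 3), nrow = 3, byrow = TRUE), fs,
              tibble::tibble(sample = 0L, code = 1L), montage_iv2b())
}

test_that("notch removes 50 Hz and the passband preserves 10 Hz", {
  trim <- 500:4500
  s50 <- make_tone_session(50, 1)
  f50 <- filter_session(s50, preprocess_spec())
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(f50$signal[1, trim]) / rms(s50$signal[1, trim]), 0.05)

  s10 <- make_tone_session(10, 1)
  f10 <- filter_session(s10, preprocess_spec())
  expect_lt(abs(rms(f10$signal[1, trim]) / rms(s10$signal[1, trim]) - 1), 0.05)
  expect_equal(ncol(f10$signal), ncol(s10$signal))   # length preserved
})

test_that("out-of-band white noise is attenuated at least 20 dB above 70 Hz", {
  set.seed(1)
  fs <- 250
  x <- rnorm(fs * 40)
  s <- raw_session(matrix(rep(x, 3), 3, byrow = TRUE), fs,
                   tibble::tibble(sample = 0L, code = 1L), montage_iv2b())
  f <- filter_session(s, preprocess_spec())
  sp <- stats::spec.pgram(stats::ts(f$signal[1, ], frequency = fs),
                          spans = 51, plot = FALSE)
  pass <- mean(sp$spec[sp$freq > 5 & sp$freq < 40])
  stopband <- mean(sp$spec[sp$freq > 70])
  expect_gt(10 * log10(pass / stopband), 20)
})

test_that("filters beyond Nyquist are rejected", {
  s <- make_tone_session(10, 1)
  expect_error(filter_session(s, preprocess_spec(bandpass_hz = c(0.5, 130))),
               "Nyquist")
})

test_that("epoching implements the half-open cue-locked window", {
  fs <- 250
  x <- matrix(as.numeric(0:(fs * 40 - 1)), 3, fs * 40, byrow = TRUE)  # ramp: x[t] = t (0-based)
  s <- raw_session(x, fs, tibble::tibble(sample = c(0L, 2500L), code = c(1L, 2L)),
                   montage_iv2b())
  ep4 <- epoch(s, preprocess_spec(window_len_s = 4))
  expect_equal(dim(ep4$data)[3], 1000L)            # 4 s at 250 Hz
  ep2 <- epoch(s, preprocess_spec(window_len_s = 2))
  expect_equal(dim(ep2$data)[3], 500L)
  # ramp signal: onset 0, start 2 s -> first epoch sample is x[500] (0-based)
  expect_equal(ep4$data[1, 1, 1], 500)
  expect_equal(ep4$data[2, 1, 1], 3000)
  # window overrun reports the offending trials
  s2 <- raw_session(x[, 1:2000], fs,
                    tibble::tibble(sample = c(0L, 1500L), code = c(1L, 1L)),
                    montage_iv2b())
  expect_error(epoch(s2, preprocess_spec(window_len_s = 4)), "trial")
})

test_that("subsampling is plain decimation keeping ceiling(L/n) samples", {
  sim <- small_session(seed = 3, n_per = 2)
  ep <- epoch(sim$session, preprocess_spec(window_len_s = 4))
  expect_identical(subsample(ep, 1), ep)           # n = 1 identity
  s2 <- subsample(ep, 2)
  expect_equal(dim(s2$data)[3], 500L)
  expect_equal(s2$data[1, 1, ], ep$data[1, 1, seq(1, 1000, by = 2)])
  expect_equal(s2$fs_effective, 125)
  # 3.5 s -> 875 samples -> n = 2 keeps 438 (indices 0, 2, ..., 874)
  ep35 <- epoch(sim$session, preprocess_spec(window_len_s = 3.5))
  expect_equal(dim(subsample(ep35, 2)$data)[3], 438L)
  expect_error(subsample(ep, 0), "configuration")
})

test_that("decimation of a slice equals slicing a decimation, and factors compose", {
  sim <- small_session(seed = 4, n_per = 2)
  pp <- preprocess_spec(window_len_s = 2)
  a <- subsample(epoch(sim$session, pp), 2)
  # manual: decimate the continuous signal first, then cut the epoch
  dec <- sim$session
  dec$signal <- dec$signal[, seq(1, ncol(dec$signal), by = 2)]
  dec$fs <- dec$fs / 2
  dec$events$sample <- as.integer(dec$events$sample / 2)
  b <- epoch(dec, pp)
  expect_equal(a$data, b$data)
  ep <- epoch(sim$session, preprocess_spec(window_len_s = 4))
  expect_equal(dim(subsample(subsample(ep, 2), 2)$data)[3],
               dim(subsample(ep, 4)$data)[3])
})

test_that("standardization uses population train statistics only", {
  sim <- small_session(seed = 6, n_per = 4)
  ep <- epoch(sim$session, preprocess_spec(window_len_s = 1))
  off <- ep
  off$data <- off$data * 0 + 2                       # constant-offset test set
  res <- standardize(ep, list(off))
  for (ch in 1:3) {
    v <- as.numeric(res$train$data[, ch, ])
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(mean(v^2) - 1), 1e-6)
  }
  # the test set is transformed with train stats, not recentred to zero
  expect_equal(unique(round(as.numeric(res$others[[1]]$data[, 1, ]), 10)),
               round((2 - res$stats$mean[1]) / res$stats$sd[1], 10))
  # hand-computed: one trial, values {1,2,3}: mean 2, population sd sqrt(2/3)
  tiny <- epoched_dataset(array(c(1, 2, 3), c(1, 1, 3)), 0L, "C3", 250)
  st <- standardize(tiny)$stats
  expect_equal(st$mean, 2)
  expect_equal(st$sd, sqrt(2 / 3))
  # zero-variance channel is named
  const <- epoched_dataset(array(5, c(2, 1, 4)), c(0L, 0L), "CZ", 250)
  expect_error(standardize(const), "CZ")
})
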