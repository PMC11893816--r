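# Simulator properties: determinism, spectral slope, ERD parameter
# recovery, the no-effect null, and benchmark-shaped splits.

test_that("identical seeds give bit-identical sessions", {
  a <- small_session(seed = 7, n_per = 3)
  b <- small_session(seed = 7, n_per = 3)
  expect_identical(a$session$signal, b$session$signal)
  expect_identical(a$truth, b$truth)
  c <- small_session(seed = 8, n_per = 3)
  expect_false(identical(a$session$signal, c$session$signal))
})

test_that("background spectral slope matches the configured 1/f exponent within 0.2", {
  for (alpha in c(0.8, 1.4)) {
    cfg <- sim_config(n_trials_per_class = 10, n_classes = 2,
                      montage = montage_iv2b(),
                      osc_bands = list(c(8, 12, 0)),     # oscillations off
                      noise = list(one_over_f_exponent = alpha, pink_sd = 1,
                                   white_sd = 0, common_sd = 0),
                      seed = 3)
    x <- simulate_session(cfg)$session$signal[1, ]
    sp <- stats::spec.pgram(stats::ts(x, frequency = 250), spans = 31,
                            plot = FALSE, taper = 0.1)
    keep <- sp$freq >= 2 & sp$freq <= 40
    slope <- stats::coef(stats::lm(log(sp$spec[keep]) ~ log(sp$freq[keep])))[2]
    expect_lt(abs(-slope - alpha), 0.2)
  }
})

test_that("with no ERD modulation, MI band power equals baseline band power", {
  cfg <- sim_config(n_trials_per_class = 50, n_classes = 2,
                    montage = montage_iv2b(),
                    erd_depth = matrix(1, 2, 3),     # null effect
                    seed = 5)
  sim <- simulate_session(cfg)
  m <- erd_percent(sim$session, band = c(8, 12))
  # per-trial paired band powers at C3: two-sided t test should not reject
  raw <- sim$session
  R <- mieeg3d:::band_power_epochs(raw, c(8, 12), c(0, 2))
  A <- mieeg3d:::band_power_epochs(raw, c(8, 12), c(3.25, 7.25))
  p <- stats::t.test(A[, 1], R[, 1], paired = TRUE)$p.value
  expect_gt(p, 0.01)
})

test_that("measured ERD converges to the closed-form power ratio", {
  # attenuation a on the oscillation in band noise: expected ERD% is
  # (a^2 P_osc + P_bg) / (P_osc + P_bg) - 1, scaled to percent. With a
  # mostly clean oscillation the -75% point of a = 0.5 is approached.
  a <- 0.5
  ed <- matrix(1, 2, 3, dimnames = list(NULL, c("C3", "CZ", "C4")))
  ed[1, "C4"] <- a                             # left-hand trials attenuate C4
  cfg <- sim_config(n_trials_per_class = 110, n_classes = 2,
                    montage = montage_iv2b(), erd_depth = ed,
                    osc_bands = list(c(8, 12, 1.0)),
                    noise = list(one_over_f_exponent = 1, pink_sd = 0.1,
                                 white_sd = 0.05, common_sd = 0),
                    seed = 9)
  sim <- simulate_session(cfg)
  # analysis interval inside the flat part of the ERD gain (ramps 0.25 s)
  m <- erd_percent(sim$session, band = c(8, 12), baseline = c(0.25, 1.75),
                   analysis = c(4, 6.75), classes = 1)
  erd_c4 <- m$erd_pct[m$channel == "C4"]
  # brute-force band power accounting for residual background in band
  raw <- sim$session
  bw <- mieeg3d:::band_power_epochs(raw, c(8, 12), c(0.25, 1.75))
  p_total <- mean(bw[, 3])
  # background-only session with the same seed structure
  cfg0 <- cfg; cfg0$osc_bands <- list(c(8, 12, 0))
  p_bg <- mean(mieeg3d:::band_power_epochs(simulate_session(cfg0)$session,
                                           c(8, 12), c(0.25, 1.75))[, 3])
  p_osc <- p_total - p_bg
  expected <- ((a^2 * p_osc + p_bg) / (p_osc + p_bg) - 1) * 100
  expect_lt(abs(erd_c4 - expected), 6)         # Monte-Carlo tolerance
  expect_lt(erd_c4, -60)                       # near the noise-free -75%
})

test_that("simulator rejects montages without lateral motor channels", {
  expect_error(sim_config(montage = montage_1010(c("FZ", "CZ", "POZ")),
                          n_classes = 2),
               "configuration error")
})

test_that("benchmark-shaped splits have the reference trial layout", {
  bench <- cached("iv2a_bench", make_benchmark_like(5, "iv2a_like"))
  expect_equal(dim(bench$train$data)[1], 288L)
  expect_equal(as.integer(table(bench$train$labels)), rep(72L, 4))
  expect_equal(dim(bench$test$data)[1], 288L)
  expect_equal(dim(bench$train$data)[3], 1000L)   # 4 s at 250 Hz

  b2 <- cached("iv2b_bench", make_benchmark_like(5, "iv2b_like"))
  expect_equal(dim(b2$train$data)[1:2], c(400L, 3L))
  expect_equal(dim(b2$test$data)[1], 320L)

  again <- make_benchmark_like(5, "iv2b_like")
  expect_identical(again$test$data, b2$test$data)
})
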