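# Montages, sessions, archives, and format adapters.

test_that("built-in montages carry the documented channel sets on the 6x7 grid", {
  m22 <- montage_22()
  expect_setequal(m22$channel,
                  c("FZ", "FC3", "FC1", "FCZ", "FC2", "FC4", "C5", "C3", "C1",
                    "CZ", "C2", "C4", "C6", "CP3", "CP1", "CPZ", "CP2", "CP4",
                    "P1", "PZ", "P2", "POZ"))
  m8 <- montage_8()
  expect_equal(m8$channel, c("C5", "C3", "CZ", "C4", "CP1", "CP2", "CP4", "POZ"))
  # bijection: unique names, unique cells, all inside the 6x7 field
  expect_false(anyDuplicated(m22$channel) > 0)
  expect_false(anyDuplicated(paste(m22$row, m22$col)) > 0)
  expect_true(all(m22$row >= 0 & m22$row <= 5 & m22$col >= 0 & m22$col <= 6))
  # frontal row 0, midline column 3
  expect_equal(m22[m22$channel == "FZ", ]$row, 0L)
  expect_equal(m22[m22$channel == "CZ", ]$col, 3L)
})

test_that("montage construction rejects duplicates and unknown channels", {
  expect_error(montage_1010(c("C3", "C3")), "unique")
  expect_error(montage_1010(c("C3", "XX9")), "XX9")
  expect_error(montage_subset(montage_8(), c("C3", "FT7")), "FT7")
})

test_that("session constructors enforce their invariants", {
  sig <- matrix(rnorm(3 * 100), 3)
  ev <- tibble::tibble(sample = c(0L, 50L), code = c(1L, 2L))
  s <- raw_session(sig, 250, ev, montage_iv2b())
  expect_s3_class(s, "raw_session")
  expect_error(raw_session(sig, 250, tibble::tibble(sample = 100L, code = 1L),
                           montage_iv2b()), "within the signal")
  sig[1, 1] <- NA
  expect_error(raw_session(sig, 250, ev, montage_iv2b()), "finite")
  expect_error(epoched_dataset(array(0, c(4, 3, 10)), labels = c(0, 1),
                               channels = c("C3", "CZ", "C4"),
                               fs_effective = 250), "labels")
})

test_that("archive round-trip is bit-exact for arrays and lossless for metadata", {
  sim <- small_session(seed = 1, n_per = 3)
  dir <- withr::local_tempdir()
  write_archive(sim$session, file.path(dir, "raw"),
                provenance = list(seed = 1, generator = "simulate_session"))
  back <- load_archive(file.path(dir, "raw"))
  expect_identical(back$signal, sim$session$signal)
  expect_identical(back$events$sample, sim$session$events$sample)
  expect_identical(back$fs, sim$session$fs)
  expect_identical(back$montage$channel, sim$session$montage$channel)
  expect_equal(attr(back, "provenance")$seed, 1)

  ep <- epoch(sim$session, preprocess_spec(window_len_s = 1))
  write_archive(ep, file.path(dir, "ep"))
  ep2 <- load_archive(file.path(dir, "ep"))
  expect_identical(ep2$data, ep$data)
  expect_identical(ep2$labels, ep$labels)
  expect_identical(ep2$window_len_s, ep$window_len_s)
})

test_that("archives written by the benchmark generator report its dimensions", {
  bench <- cached("iv2a_bench", make_benchmark_like(5, "iv2a_like"))
  dir <- withr::local_tempdir()
  write_archive(bench$train, file.path(dir, "a"))
  tr <- load_archive(file.path(dir, "a"))
  expect_equal(dim(tr$data)[1:2], c(288L, 22L))
  expect_equal(tr$fs_effective, 250)
})

test_that("corrupt archives raise format or integrity errors", {
  sim <- small_session(seed = 2, n_per = 2)
  dir <- withr::local_tempdir()
  expect_error(load_archive(file.path(dir, "nothere")), "sidecar")
  ep <- epoch(sim$session, preprocess_spec(window_len_s = 1))
  write_archive(ep, file.path(dir, "bad"))
  arr <- readRDS(file.path(dir, "bad", "arrays.rds"))
  arr$labels <- arr$labels[-1]               # labels length != trials
  saveRDS(arr, file.path(dir, "bad", "arrays.rds"))
  expect_error(load_archive(file.path(dir, "bad")), "integrity")
})

test_that("EDF adapter reorders to montage, extracts trigger events, errors on missing channels", {
  fs <- 250
  n <- 12 * fs
  sig <- rbind(round(1000 * sin(2 * pi * 10 * (1:n) / fs)),
               round(500 * cos(2 * pi * 5 * (1:n) / fs)),
               round(rnorm(n, sd = 100)),
               rep(0, n))
  sig[4, c(501, 2501)] <- c(1, 2)            # trigger channel pulses
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf_fixture(f, c("CZ", "C3", "C4", "TRIG"), sig, fs)
  ses <- adapt_external(f, "edf", montage_iv2b())
  expect_equal(nrow(ses$signal), 3L)
  expect_equal(rownames(ses$signal), c("C3", "CZ", "C4"))
  # channel reorder: C3 row of the session is file row 2
  expect_equal(as.numeric(ses$signal["C3", 1:100]), sig[2, 1:100])
  expect_equal(ses$events$sample, c(500L, 2500L))
  expect_equal(ses$events$code, c(1L, 2L))
  expect_error(adapt_external(f, "edf", montage_8()), "C5")
})

test_that("GDF adapter reads signals and the native event table", {
  fs <- 250
  n <- 4 * fs
  sig <- rbind(round(800 * sin(2 * pi * 12 * (1:n) / fs)),
               round(rnorm(n, sd = 50)),
               round(rnorm(n, sd = 50)))
  ev <- tibble::tibble(sample = c(100L, 600L), code = c(769L, 770L))
  f <- withr::local_tempfile(fileext = ".gdf")
  write_gdf_fixture(f, c("C4", "C3", "CZ"), sig, fs, ev)
  ses <- adapt_external(f, "gdf", montage_iv2b(),
                        event_code_map = c("769" = 1, "770" = 2))
  expect_equal(rownames(ses$signal), c("C3", "CZ", "C4"))
  expect_equal(as.numeric(ses$signal["C4", 1:50]), sig[1, 1:50])
  expect_equal(ses$events$sample, c(100L, 600L))
  expect_equal(ses$events$code, c(1L, 2L))
})
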