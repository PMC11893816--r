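# Accuracy maintenance, Pareto front, sweeps.
# (The full channel-elimination recovery runs in the acceptance suite.)

test_that("accuracy maintenance compares candidate max against baseline min", {
  base <- cv_result(c(0.7299, 0.75, 0.80, 0.78, 0.82))
  expect_true(accuracy_maintained(base, base))              # max >= own min
  expect_true(accuracy_maintained(cv_result(c(0.70, 0.71, 0.74, 0.72, 0.73)), base))
  expect_false(accuracy_maintained(cv_result(c(0.65, 0.66, 0.70, 0.68, 0.69)), base))
  # monotone: raising any fold accuracy never flips true -> false
  cand <- cv_result(c(0.70, 0.71, 0.74, 0.72, 0.73))
  stopifnot(accuracy_maintained(cand, base))
  for (i in 1:5) {
    up <- cand$fold_acc
    up[i] <- min(1, up[i] + 0.1)
    expect_true(accuracy_maintained(cv_result(up), base))
  }
})

test_that("pareto front equals the brute-force dominance filter", {
  simple <- tibble::tibble(n_parameters = c(10, 20, 30),
                           accuracy = c(0.5, 0.6, 0.55))
  pf <- pareto_front(simple)
  expect_equal(pf$n_parameters, c(10, 20))
  expect_equal(pf$accuracy, c(0.5, 0.6))
  expect_equal(nrow(pareto_front(simple[2, ])), 1L)          # single point

  set.seed(23)
  for (rep in 1:3) {
    pts <- tibble::tibble(
      n_parameters = sample(100:5000, 1000, replace = TRUE),
      accuracy = round(runif(1000, 0.2, 0.95), 3))
    pf <- pareto_front(pts)
    oracle <- pareto_oracle(pts)
    expect_equal(pf$n_parameters, oracle$n_parameters)
    expect_equal(sort(pf$accuracy), sort(oracle$accuracy))
    expect_true(all(diff(pf$accuracy) > 0))                  # strictly increasing
    expect_true(all(diff(pf$n_parameters) >= 0))
  }
})

test_that("subsample sweep reports the effective-rate grid and n=1 equals plain CV", {
  sim <- cached("sweep_small", {
    mk <- function(s) simulate_session(sim_config(
      n_trials_per_class = 10, n_classes = 2, montage = montage_iv2b(),
      depth = 0.4, seed = s,
      noise = list(one_over_f_exponent = 1, pink_sd = 0.5, white_sd = 0.15,
                   common_sd = 0.2)))$session
    list(train = mk(41), test = mk(42))
  })
  spec <- eegnet_spec(K_l = 8, F1 = 2, K_l2 = 4, n_classes = 2)
  cfg <- screening_config(max_epochs = 6, early_stop_patience = 5, shuffle_seed = 2)
  pp <- preprocess_spec(window_len_s = 2)
  sw <- subsample_sweep(sim, spec, ns = 1:5, pp_spec = pp, cfg = cfg)
  expect_equal(nrow(sw), 5L)
  expect_equal(sw$fs_effective, 250 / (1:5))
  expect_true(all(diff(sw$n_samples) < 0))
  # the n = 1 row reproduces a standalone cross-validation run
  eps <- lapply(sim, function(s) epoch(filter_session(s, pp), pp))
  std <- standardize(eps$train, list(eps$test))
  cfg1 <- cfg
  cfg1$shuffle_seed <- derive_seed(cfg$shuffle_seed, "sweep-s1")
  cv1 <- crossval_5fold(std$train, std$others[[1]], spec, cfg1)
  expect_equal(sw$mean[1], cv1$mean)
})

test_that("window sweep returns one row per window with monotone sample counts", {
  sim <- cached("sweep_small", stop("fixture must exist"))
  spec <- eegnet_spec(K_l = 8, F1 = 2, K_l2 = 4, n_classes = 2)
  cfg <- screening_config(max_epochs = 5, early_stop_patience = 4, shuffle_seed = 3)
  sw <- window_sweep(sim, spec, windows = c(4, 3, 2, 1),
                     pp_spec = preprocess_spec(subsample_n = 2), cfg = cfg)
  expect_equal(nrow(sw), 4L)
  expect_true(all(diff(sw$n_samples[order(-sw$window_len_s)]) < 0))
  expect_type(sw$maintained, "logical")
  # the longest window is the default baseline, hence trivially maintained
  expect_true(sw$maintained[sw$window_len_s == 4])
})

test_that("elimination protocol: phase-1 combinatorics and recovery of informative channels", {
  # synthetic evaluation backend: accuracy depends only on whether the
  # informative channels are present, so the expected outcome is known
  dummy <- function(chs) {
    epoched_dataset(array(0, c(4, length(chs), 8)), labels = c(0L, 1L, 0L, 1L),
                    channels = chs, fs_effective = 250)
  }
  score_fn <- function(chs, reps, seed_tag) {
    base <- 0.5 + 0.15 * ("C3" %in% chs) + 0.15 * ("C4" %in% chs)
    jitter <- (sum(utf8ToInt(paste(chs, collapse = ""))) %% 7) / 1000
    list(cv_result(pmin(1, base + jitter + c(-0.01, -0.005, 0, 0.005, 0.01))))
  }
  chs22 <- montage_22()$channel
  trace <- channel_elimination_search(
    list(train = dummy(chs22), test = dummy(chs22)),
    proposed_3dcnn_spec(n_classes = 2),
    selection_protocol(candidate_reps = 1, confirm_reps = 1),
    screening_config(), eval_fn = score_fn)
  # n = 22 combinatorial step evaluates all C(22, 20) = 231 subsets
  expect_equal(nrow(trace$steps$candidates[[1]]), 231L)
  # two channels are removed per combinatorial step: 22 -> 20 -> ... -> 10
  p1 <- trace$steps[trace$steps$n_channels >= 10, ]
  expect_equal(diff(c(22L, p1$n_channels)), rep(-2L, nrow(p1)))
  # the informative pair survives to the final set
  expect_true(all(c("C3", "C4") %in% trace$final_channels))
  # every removal is justified by a recorded reason and candidate table
  expect_true(all(nchar(trace$steps$reason) > 0))
  expect_true(all(vapply(trace$steps$candidates, nrow, 0L) > 0))
  # channel count strictly decreases along the trace
  expect_true(all(diff(trace$steps$n_channels) < 0))
})

test_that("elimination search on 3 channels evaluates pairs then singletons", {
  dummy <- function(chs) {
    epoched_dataset(array(0, c(4, length(chs), 8)), labels = c(0L, 1L, 0L, 1L),
                    channels = chs, fs_effective = 250)
  }
  score_fn <- function(chs, reps, seed_tag) {
    base <- 0.5 + 0.2 * ("C3" %in% chs) + 0.2 * ("C4" %in% chs)
    list(cv_result(base + c(-0.01, 0, 0, 0, 0.01)))
  }
  chs <- montage_iv2b()$channel              # C3, CZ, C4
  trace <- channel_elimination_search(
    list(train = dummy(chs), test = dummy(chs)),
    proposed_3dcnn_spec(n_classes = 2),
    selection_protocol(candidate_reps = 1, confirm_reps = 1),
    screening_config(), eval_fn = score_fn)
  # first step evaluates the C(3,2) = 3 pairs
  expect_equal(nrow(trace$steps$candidates[[1]]), 3L)
  expect_equal(trace$final_channels, c("C3", "C4"))
  expect_match(trace$termination, "no longer maintained")
  # budget exhaustion yields a partial trace with an explicit reason
  tr2 <- channel_elimination_search(
    list(train = dummy(chs), test = dummy(chs)),
    proposed_3dcnn_spec(n_classes = 2),
    selection_protocol(candidate_reps = 1, confirm_reps = 1, max_evals = 1),
    screening_config(), eval_fn = score_fn)
  expect_match(tr2$termination, "budget")
})
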