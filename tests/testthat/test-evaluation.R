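# Cross-validation mechanics, Cohen's kappa, Wilcoxon signed-rank.

test_that("cv_result summarises fold accuracies correctly", {
  cv <- cv_result(c(0.6, 0.7, 0.8, 0.7, 0.7))
  expect_equal(cv$mean, 0.7)
  expect_equal(cv$min, 0.6)
  expect_equal(cv$max, 0.8)
  expect_equal(glance(cv)$n_folds, 5L)
  expect_equal(nrow(tidy(cv)), 5L)
  expect_error(cv_result(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("stratified folds preserve class proportions within one trial", {
  labels <- rep(0:3, times = c(23, 22, 21, 24))
  fold <- mieeg3d:::stratified_folds(labels, 5L, seed = 3)
  for (cl in 0:3) {
    per_fold <- table(factor(fold[labels == cl], levels = 1:5))
    expect_lte(diff(range(per_fold)), 1)
  }
  # all trials assigned exactly once
  expect_equal(sort(unique(fold)), 1:5)
  expect_error(crossval_5fold(
    epoched_dataset(array(rnorm(8 * 2 * 16), c(8, 2, 16)),
                    labels = c(rep(0L, 6), 1L, 1L),
                    channels = c("C3", "C4"), fs_effective = 250),
    NULL, NULL), "stratification")
})

test_that("Cohen's kappa matches hand-computed values", {
  expect_equal(cohen_kappa(diag(c(10, 5, 7, 3))), 1)          # perfect
  expect_equal(cohen_kappa(matrix(4, 4, 4)), 0)               # chance
  expect_equal(cohen_kappa(matrix(c(30, 10, 10, 30), 2, 2)), 0.5)
  expect_warning(k <- cohen_kappa(matrix(c(5, 0, 0, 0), 2, 2)), "degenerate")
  expect_true(is.nan(k))
  expect_error(cohen_kappa(matrix(1, 2, 3)), "square")
})

test_that("exact Wilcoxon p-values agree with the sign-pattern enumeration", {
  # all-positive differences, n = 9: p = 2 / 2^9
  a <- 1:9 + 0.5
  b <- rep(0, 9) + c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06, 0.07, 0.08, 0.09)
  res <- wilcoxon_signed_rank(a, b)
  expect_equal(res$p_value, 0.00390625)
  expect_equal(res$p_value, wilcoxon_exact_oracle(a, b))
  expect_match(res$method, "exact")
  # random untied data, several n: implementation equals enumeration
  set.seed(13)
  for (n in c(6, 10, 14)) {
    x <- rnorm(n)
    y <- x + rnorm(n, 0.3)
    expect_equal(wilcoxon_signed_rank(y, x)$p_value,
                 wilcoxon_exact_oracle(y, x), tolerance = 1e-10)
  }
})

test_that("normal approximation stays close to the exact distribution at n = 20", {
  set.seed(17)
  x <- rnorm(20)
  y <- x + rnorm(20, 0.25)
  exact_p <- wilcoxon_exact_oracle(y, x)
  approx_p <- suppressWarnings(
    stats::wilcox.test(y, x, paired = TRUE, exact = FALSE, correct = FALSE)$p.value)
  expect_lt(abs(exact_p - approx_p), 0.02)
})

test_that("degenerate Wilcoxon inputs are reported, and nulls give large p", {
  expect_warning(res <- wilcoxon_signed_rank(1:6, 1:6), "undefined")
  expect_true(is.na(res$p_value))
  a <- seq(0.1, 0.9, length.out = 9)
  res <- wilcoxon_signed_rank(a, a + 0.001 * c(-1, 1, -1, 1, -1, 1, -1, 1, -1))
  expect_gt(res$p_value, 0.5)
})

test_that("cross-validation is reproducible and reports per-fold confusions", {
  sim <- cached("cv_small", {
    s <- small_session(seed = 21, n_per = 12, depth = 0.4,
                       noise = list(one_over_f_exponent = 1, pink_sd = 0.5,
                                    white_sd = 0.15, common_sd = 0.2))
    pp <- preprocess_spec(window_len_s = 1, subsample_n = 2)
    ep <- subsample(epoch(filter_session(s$session, pp), pp), 2)
    standardize(ep)$train
  })
  spec <- eegnet_spec(K_l = 8, F1 = 2, K_l2 = 4, n_classes = 2)
  cfg <- screening_config(max_epochs = 8, early_stop_patience = 7, shuffle_seed = 5)
  cv1 <- crossval_5fold(sim, sim, spec, cfg)
  cv2 <- crossval_5fold(sim, sim, spec, cfg)
  expect_identical(cv1$fold_acc, cv2$fold_acc)
  expect_length(cv1$fold_acc, 5L)
  expect_true(all(vapply(cv1$confusions, sum, 0) == dim(sim$data)[1]))
  expect_true(cv1$min <= cv1$mean && cv1$mean <= cv1$max)
})
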