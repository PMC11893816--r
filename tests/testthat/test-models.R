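# Layer graphs: published parameter totals, closed forms, forward-pass
# contracts, gradient correctness, and trainability.

test_that("builders reproduce the published parameter totals", {
  expect_equal(count_parameters(build_eegnet(eegnet_spec(), 22, 1000)), 3444)
  expect_equal(count_parameters(build_eegnet(eegnet_spec(n_classes = 2), 3, 1000)), 2146)
  expect_equal(count_parameters(build_eegnet(eegnet_spec(), 8, 250)), 1684)
  expect_equal(count_parameters(
    build_eegnet(eegnet_spec(K_l = 16, F1 = 4, K_l2 = 16, n_classes = 2), 2, 187)), 394)
  expect_equal(count_parameters(
    build_proposed_3dcnn(proposed_3dcnn_spec(K_s = 1, K_l = 4, F1 = 8), 3, 3, 500)), 1524)
})

test_that("graph parameter totals equal the closed forms for random specs", {
  set.seed(42)
  for (i in 1:50) {
    K_l <- sample(c(2, 4, 8, 16), 1); F1 <- sample(c(1, 2, 4, 8), 1)
    K_s <- sample(1:3, 1); N <- sample(c(2, 4), 1)
    C1 <- sample(1:3, 1); C2 <- sample(2:4, 1)
    T <- sample(c(64, 128, 192, 256), 1)
    mp <- build_proposed_3dcnn(
      proposed_3dcnn_spec(K_s = K_s, K_l = K_l, F1 = F1, n_classes = N), C1, C2, T)
    expect_equal(count_parameters(mp),
                 params_proposed_closed_form(C1, C2, K_l, K_s, F1, 2, T, N))
    C <- sample(2:8, 1); K_l2 <- sample(c(2, 4, 8, 16), 1)
    me <- build_eegnet(eegnet_spec(K_l = K_l, F1 = F1, K_l2 = K_l2, n_classes = N), C, T)
    expect_equal(count_parameters(me),
                 params_eegnet_closed_form(C, K_l, F1, 2, K_l2, T, N))
  }
})

test_that("flatten width and degenerate-T are handled as specified", {
  m <- build_proposed_3dcnn(proposed_3dcnn_spec(K_s = 1, K_l = 4, F1 = 8), 3, 3, 500)
  dl <- m$layers[[length(m$layers)]]
  expect_equal(dl$in_maps * dl$in_T, 16 * (500 %/% 64))   # flatten width 112
  expect_error(build_proposed_3dcnn(proposed_3dcnn_spec(), 3, 3, 63), "63")
  # alternative pooling interpretation (printed pool sizes 4 then 8)
  m48 <- build_proposed_3dcnn(proposed_3dcnn_spec(K_s = 1, K_l = 4, F1 = 8,
                                                  pool_factors = c(4, 8)),
                              3, 3, 500)
  dl48 <- m48$layers[[length(m48$layers)]]
  expect_equal(dl48$in_T, 500 %/% 32)
})

test_that("forward returns deterministic probability rows summing to one", {
  m <- build_proposed_3dcnn(proposed_3dcnn_spec(K_s = 1, K_l = 4, F1 = 4), 2, 2, 128)
  x <- array(rnorm(4 * 128 * 64), c(4, 128, 64))
  p1 <- forward(m, x)
  p2 <- forward(m, x)
  expect_identical(p1, p2)                        # eval mode is deterministic
  expect_equal(dim(p1), c(64L, 4L))               # one row per batch element
  expect_equal(rowSums(p1), rep(1, 64), tolerance = 1e-6)
  # all-zero input: softmax of the bias vector, equal across batch rows
  z <- forward(m, array(0, c(4, 128, 2)))
  expect_equal(z[1, ], z[2, ])
  expect_equal(sum(z[1, ]), 1, tolerance = 1e-6)
  expect_error(forward(m, array(0, c(5, 128, 2))), "shape mismatch")
})

test_that("backpropagation matches finite differences for both architectures", {
  set.seed(7)
  check_grads <- function(m, M, T, K) {
    x <- array(rnorm(M * T * 3), c(M, T, 3))
    y <- sample(0:(K - 1), 3, replace = TRUE)
    loss_of <- function(model) {
      r <- mieeg3d:::graph_forward(model, x, "train")
      mieeg3d:::softmax_xent(r$logits, y)$loss
    }
    r <- mieeg3d:::graph_forward(m, x, "train")
    gr <- mieeg3d:::graph_backward(m, r$caches, mieeg3d:::softmax_xent(r$logits, y)$grad)
    worst <- 0
    for (li in seq_along(m$layers)) for (pn in names(m$layers[[li]]$params)) {
      p <- m$layers[[li]]$params[[pn]]
      for (j in sample(length(p), min(3, length(p)))) {
        mp <- m; mp$layers[[li]]$params[[pn]][j] <- p[j] + 1e-5
        mm <- m; mm$layers[[li]]$params[[pn]][j] <- p[j] - 1e-5
        num <- (loss_of(mp) - loss_of(mm)) / 2e-5
        ana <- gr[[li]][[pn]][j]
        worst <- max(worst, abs(num - ana) / max(1e-6, abs(num) + abs(ana)))
      }
    }
    worst
  }
  m1 <- build_proposed_3dcnn(
    proposed_3dcnn_spec(K_s = 2, K_l = 3, F1 = 2, n_classes = 2, dropout = 0),
    2, 2, 70, init_seed = 3)
  expect_lt(check_grads(m1, 4, 70, 2), 1e-4)
  m2 <- build_eegnet(eegnet_spec(K_l = 8, F1 = 2, K_l2 = 4, n_classes = 2,
                                 dropout = 0), 3, 64, init_seed = 5)
  expect_lt(check_grads(m2, 3, 64, 2), 1e-4)
})

test_that("training drives accuracy to 1 on linearly separable grids", {
  set.seed(9)
  mk <- function(n) {
    y <- rep(0:1, each = n / 2)
    x <- array(rnorm(4 * 96 * n, sd = 0.3), c(n, 2, 2, 96))
    x[y == 1, 1, 1, ] <- x[y == 1, 1, 1, ] + 1.5    # mean shift on one cell
    structure(list(values = x, labels = y, n_classes = 2L,
                   layout = NULL, fs_effective = 96),
              class = "grid_dataset")
  }
  tr <- mk(40); va <- mk(16)
  spec <- proposed_3dcnn_spec(K_s = 1, K_l = 4, F1 = 2, n_classes = 2)
  fit <- train_model(tr, va, spec,
                     train_config(max_epochs = 60, early_stop_patience = 59,
                                  batch_size = 20, shuffle_seed = 1))
  p <- predict(fit$model, tr)
  expect_equal(mean(p == tr$labels), 1)
})

test_that("identical training seeds reproduce identical weights", {
  set.seed(1)
  mk <- function(n, seed) {
    set.seed(seed)
    structure(list(values = array(rnorm(4 * 64 * n), c(n, 2, 2, 64)),
                   labels = rep(0:1, length.out = n), n_classes = 2L,
                   layout = NULL, fs_effective = 64),
              class = "grid_dataset")
  }
  tr <- mk(12, 5); va <- mk(8, 6)
  spec <- proposed_3dcnn_spec(K_s = 1, K_l = 4, F1 = 2, n_classes = 2)
  cfg <- train_config(max_epochs = 5, early_stop_patience = 4, shuffle_seed = 3)
  f1 <- train_model(tr, va, spec, cfg)
  f2 <- train_model(tr, va, spec, cfg)
  expect_identical(lapply(f1$model$layers, `[[`, "params"),
                   lapply(f2$model$layers, `[[`, "params"))
  expect_identical(f1$history, f2$history)
})

test_that("early stopping halts once validation stops improving", {
  set.seed(2)
  mk <- function(n, seed) {
    set.seed(seed)
    structure(list(values = array(rnorm(4 * 64 * n), c(n, 2, 2, 64)),
                   labels = rep(0:1, length.out = n), n_classes = 2L,
                   layout = NULL, fs_effective = 64),
              class = "grid_dataset")
  }
  # pure-noise validation: loss cannot keep improving, patience must bite
  fit <- train_model(mk(12, 1), mk(8, 2),
                     proposed_3dcnn_spec(K_s = 1, K_l = 4, F1 = 2, n_classes = 2),
                     train_config(max_epochs = 200, early_stop_patience = 3,
                                  shuffle_seed = 4))
  expect_lt(nrow(fit$history), 200)
  expect_equal(fit$best_epoch, which.min(fit$history$val_loss))
})
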