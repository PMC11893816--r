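# Training: mini-batch Adam with cross-entropy loss and early stopping on
# validation loss (best-epoch snapshot restored). All randomness (weight
# init, shuffling, dropout) flows from one seed, so identical
# configurations reproduce identical weights.

#' Training configuration
#'
#' @param max_epochs Maximum training epochs.
#' @param early_stop_patience Stop after this many epochs without a new
#'   best validation loss (must be < `max_epochs`).
#' @param batch_size Mini-batch size.
#' @param lr Adam learning rate.
#' @param shuffle_seed Seed governing init, shuffling and dropout; the same
#'   seed is used throughout training.
#' @return A list of class `train_config`.
#' @export
train_config <- function(max_epochs = 3000, early_stop_patience = 300,
                         batch_size = 64, lr = 1e-3, shuffle_seed = 1L) {
  assert_that(early_stop_patience < max_epochs,
              "early_stop_patience must be below max_epochs")
  assert_that(is_count(batch_size), "batch_size must be a positive integer")
  structure(list(max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 batch_size = as.integer(batch_size), lr = lr,
                 shuffle_seed = as.integer(shuffle_seed)),
            class = "train_config")
}

#' Reduced-budget screening configuration
#'
#' Same protocol as [train_config()] with a small epoch budget, intended
#' for candidate ranking inside combinatorial searches where hundreds of
#' fits are needed.
#'
#' @param max_epochs,early_stop_patience,batch_size,lr,shuffle_seed See
#'   [train_config()].
#' @return A `train_config`.
#' @export
screening_config <- function(max_epochs = 40, early_stop_patience = 15,
                             batch_size = 64, lr = 2e-3, shuffle_seed = 1L) {
  train_config(max_epochs, early_stop_patience, batch_size, lr, shuffle_seed)
}

model_params_flat <- function(model) {
  lapply(model$layers, function(l) l$params)
}

# build the right graph for a dataset: grid datasets get the 3D-CNN input
# shape, channel datasets the EEGNet shape
build_for_data <- function(spec, data, init_seed) {
  if (inherits(spec, "proposed_3dcnn_spec")) {
    assert_that(inherits(data, "grid_dataset"),
                "proposed 3D-CNN needs map_to_grid() output")
    d <- dim(data$values)
    build_proposed_3dcnn(spec, d[2], d[3], d[4], init_seed = init_seed)
  } else if (inherits(spec, "eegnet_spec")) {
    assert_that(inherits(data, "epoched_dataset"),
                "EEGNet needs an epoched_dataset")
    d <- dim(data$data)
    build_eegnet(spec, d[2], d[3], init_seed = init_seed)
  } else stop("unknown model spec", call. = FALSE)
}

data_labels <- function(data) data$labels

#' Train a model
#'
#' Builds the layer graph for `spec` (unless a prebuilt `model` is given),
#' then runs mini-batch Adam on the cross-entropy loss, monitoring
#' validation loss each epoch. Training stops at `max_epochs` or after
#' `early_stop_patience` epochs without improvement; the best-validation
#' snapshot is restored.
#'
#' @param train,val Disjoint `grid_dataset`s (for the 3D-CNN) or
#'   [epoched_dataset()]s (for EEGNet), with labels.
#' @param spec A [proposed_3dcnn_spec()] or [eegnet_spec()].
#' @param cfg A [train_config()].
#' @param model Optional prebuilt `model_graph` (its weights are the
#'   starting point; the RNG is still seeded from `cfg`).
#' @return List of class `trained_model`: `model` (best snapshot),
#'   `history` (tibble: epoch, train_loss, val_loss, val_acc),
#'   `best_epoch`.
#' @export
train_model <- function(train, val, spec, cfg = train_config(), model = NULL) {
  stopifnot(inherits(cfg, "train_config"))
  if (is.null(model)) model <- build_for_data(spec, train, init_seed = cfg$shuffle_seed)
  set.seed(cfg$shuffle_seed)

  xtr <- model_input_array(model, train)
  ytr <- data_labels(train)
  xva <- model_input_array(model, val)
  yva <- data_labels(val)
  n <- dim(xtr)[3]

  # Adam state per layer/param
  mstate <- lapply(model$layers, function(l) lapply(l$params, function(p) p * 0))
  vstate <- mstate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0

  best_loss <- Inf; best_layers <- model$layers; best_epoch <- 0L; wait <- 0L
  hist <- vector("list", cfg$max_epochs)

  for (ep in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    tr_loss <- 0; nb <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- xtr[, , idx, drop = FALSE]
      fw <- graph_forward(model, xb, mode = "train")
      model <- fw$model
      ls <- softmax_xent(fw$logits, ytr[idx])
      if (!is.finite(ls$loss))
        stop("training diverged: non-finite loss at epoch ", ep, call. = FALSE)
      grads <- graph_backward(model, fw$caches, ls$grad)
      step <- step + 1
      corr <- cfg$lr * sqrt(1 - b2^step) / (1 - b1^step)
      for (i in seq_along(model$layers)) {
        for (pn in names(grads[[i]])) {
          g <- grads[[i]][[pn]]
          mstate[[i]][[pn]] <- b1 * mstate[[i]][[pn]] + (1 - b1) * g
          vstate[[i]][[pn]] <- b2 * vstate[[i]][[pn]] + (1 - b2) * g^2
          model$layers[[i]]$params[[pn]] <- model$layers[[i]]$params[[pn]] -
            corr * mstate[[i]][[pn]] / (sqrt(vstate[[i]][[pn]]) + eps)
        }
      }
      tr_loss <- tr_loss + ls$loss; nb <- nb + 1
    }
    fv <- graph_forward(model, xva, mode = "eval")
    lv <- softmax_xent(fv$logits, yva)
    acc <- mean((max.col(t(lv$probs), ties.method = "first") - 1L) == yva)
    hist[[ep]] <- c(epoch = ep, train_loss = tr_loss / nb,
                    val_loss = lv$loss, val_acc = acc)
    if (lv$loss < best_loss - 1e-9) {
      best_loss <- lv$loss; best_layers <- model$layers
      best_epoch <- ep; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$early_stop_patience) break
    }
  }
  model$layers <- best_layers
  hist <- tibble::as_tibble(do.call(rbind, hist[!vapply(hist, is.null, TRUE)]))
  structure(list(model = model, history = hist, best_epoch = best_epoch,
                 config = cfg),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model %s> best epoch %d (val loss %.4f)\n",
              x$model$kind, x$best_epoch,
              min(x$history$val_loss)))
  invisible(x)
}
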