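# Model builders: the compact 3D-CNN for grid-tensor input and the
# reference EEGNet. Both are expressed as explicit layer graphs so that
# parameters can be enumerated, MACCs instrumented, and the forward pass
# evaluated without any external deep-learning runtime.

#' Specification of the compact 3D-CNN
#'
#' Block 1 applies a single 3D convolution whose kernel spans the whole
#' `C1 x C2` electrode grid and `K_l` time samples, producing `D * F1`
#' feature maps (spatial extent fully consumed, temporal extent preserved),
#' with bias; batch-norm, ELU, temporal max-pool by 8 and dropout follow.
#' Block 2 is a separable convolution: a depthwise temporal convolution of
#' kernel length `C1 * C2 * K_s` (no bias; after block 1 the spatial
#' dimensions are degenerate, so the kernel-extension coefficient `K_s`
#' enters only through this length) followed by a pointwise convolution to
#' `F2` maps (with bias), then batch-norm, ELU, max-pool by 8, dropout.
#' Block 3 flattens to `F2 * floor(T/64)` features and classifies with a
#' dense softmax layer.
#'
#' @param K_s Kernel extension coefficient (1, 2 or 3).
#' @param K_l Temporal kernel length of the first convolution.
#' @param F1 Number of temporal filters.
#' @param D Depth multiplier (2 in all reported configurations).
#' @param dropout Dropout probability.
#' @param n_classes Number of output classes.
#' @param pool_factors Temporal pooling factors of blocks 1 and 2. The
#'   default `c(8, 8)` reproduces the printed `T/8` and `T/64` activation
#'   lengths (and the published parameter totals); `c(4, 8)` implements the
#'   literal printed pool sizes instead.
#' @return A list of class `proposed_3dcnn_spec` (with `F2 = F1 * D`).
#' @export
proposed_3dcnn_spec <- function(K_s = 2, K_l = 16, F1 = 16, D = 2,
                                dropout = 0.5, n_classes = 4,
                                pool_factors = c(8, 8)) {
  assert_that(K_s %in% 1:3, "K_s must be 1, 2 or 3")
  for (v in c(K_l, F1, D, n_classes)) assert_that(is_count(v), "spec fields must be positive integers")
  structure(list(K_s = as.integer(K_s), K_l = as.integer(K_l),
                 F1 = as.integer(F1), D = as.integer(D),
                 F2 = as.integer(F1 * D), dropout = dropout,
                 n_classes = as.integer(n_classes),
                 pool_factors = as.integer(pool_factors)),
            class = "proposed_3dcnn_spec")
}

#' Specification of the reference EEGNet
#'
#' The canonical compact convolutional network: temporal convolution
#' (`F1` filters, kernel `(1, K_l)`, same padding, no bias), batch-norm;
#' depthwise spatial convolution over all channels (depth `D`, no bias),
#' batch-norm, ELU, average-pool 4, dropout; separable convolution
#' (depthwise `(1, K_l2)` + pointwise to `F2`, both bias-free), batch-norm,
#' ELU, average-pool 8, dropout; dense softmax classifier over
#' `F2 * floor(T/32)` features.
#'
#' @param K_l Temporal kernel length (default 64).
#' @param F1 Temporal filter count (default 8).
#' @param D Depth multiplier (default 2); `F2 = F1 * D`.
#' @param K_l2 Separable (depthwise) kernel length (default 16).
#' @param dropout Dropout probability.
#' @param n_classes Number of output classes.
#' @return A list of class `eegnet_spec`.
#' @export
eegnet_spec <- function(K_l = 64, F1 = 8, D = 2, K_l2 = 16,
                        dropout = 0.5, n_classes = 4) {
  for (v in c(K_l, F1, D, K_l2, n_classes)) assert_that(is_count(v), "spec fields must be positive integers")
  structure(list(K_l = as.integer(K_l), F1 = as.integer(F1), D = as.integer(D),
                 F2 = as.integer(F1 * D), K_l2 = as.integer(K_l2),
                 dropout = dropout, n_classes = as.integer(n_classes)),
            class = "eegnet_spec")
}

new_model_graph <- function(layers, kind, spec, input) {
  structure(list(layers = layers, kind = kind, spec = spec, input = input,
                 n_classes = spec$n_classes),
            class = "model_graph")
}

#' Build the compact 3D-CNN layer graph
#'
#' @param spec A [proposed_3dcnn_spec()].
#' @param C1,C2 Grid rows and columns of the input tensor.
#' @param T Number of time samples (must leave `floor(T/64) >= 1` features
#'   after the two pooling stages).
#' @param init_seed Seed for weight initialization (uniform fan-in scaling).
#' @return A `model_graph`.
#' @export
build_proposed_3dcnn <- function(spec, C1, C2, T, init_seed = 1L) {
  stopifnot(inherits(spec, "proposed_3dcnn_spec"))
  p <- spec$pool_factors
  T1 <- T %/% p[1]
  T2 <- T1 %/% p[2]
  if (T2 < 1)
    stop("configuration error: T = ", T, " leaves an empty flatten ",
         "(floor(T/", p[1] * p[2], ") = 0)", call. = FALSE)
  C <- C1 * C2
  M1 <- spec$D * spec$F1
  set.seed(init_seed)
  layers <- list(
    layer_conv_full(C, M1, spec$K_l, T, bias = TRUE),
    layer_batchnorm(1L, M1, T),
    layer_elu(1L, M1, T),
    layer_pool(1L, M1, T, p[1], "max"),
    layer_dropout(1L, M1, T1, spec$dropout),
    layer_conv_dw_time(M1, C * spec$K_s, T1),
    layer_conv_pointwise(M1, spec$F2, T1, bias = TRUE),
    layer_batchnorm(1L, spec$F2, T1),
    layer_elu(1L, spec$F2, T1),
    layer_pool(1L, spec$F2, T1, p[2], "max"),
    layer_dropout(1L, spec$F2, T2, spec$dropout),
    layer_dense(1L, spec$F2, T2, spec$n_classes)
  )
  new_model_graph(layers, "proposed_3dcnn", spec,
                  list(kind = "grid", C1 = as.integer(C1), C2 = as.integer(C2),
                       T = as.integer(T)))
}

#' Build the reference EEGNet layer graph
#'
#' @param spec An [eegnet_spec()].
#' @param n_channels Number of EEG channels.
#' @param T Number of time samples (needs `floor(T/32) >= 1`).
#' @param init_seed Seed for weight initialization.
#' @return A `model_graph`.
#' @export
build_eegnet <- function(spec, n_channels, T, init_seed = 1L) {
  stopifnot(inherits(spec, "eegnet_spec"))
  T1 <- T %/% 4L
  T2 <- T1 %/% 8L
  if (T2 < 1)
    stop("configuration error: T = ", T, " leaves an empty flatten ",
         "(floor(T/32) = 0)", call. = FALSE)
  C <- as.integer(n_channels)
  set.seed(init_seed)
  layers <- list(
    layer_conv_temporal(C, spec$F1, spec$K_l, T),
    layer_batchnorm(C, spec$F1, T),
    layer_conv_spatial_dw(C, spec$F1, spec$D, T),
    layer_batchnorm(1L, spec$F2, T),
    layer_elu(1L, spec$F2, T),
    layer_pool(1L, spec$F2, T, 4L, "avg"),
    layer_dropout(1L, spec$F2, T1, spec$dropout),
    layer_conv_dw_time(spec$F2, spec$K_l2, T1),
    layer_conv_pointwise(spec$F2, spec$F2, T1, bias = FALSE),
    layer_batchnorm(1L, spec$F2, T1),
    layer_elu(1L, spec$F2, T1),
    layer_pool(1L, spec$F2, T1, 8L, "avg"),
    layer_dropout(1L, spec$F2, T2, spec$dropout),
    layer_dense(1L, spec$F2, T2, spec$n_classes)
  )
  new_model_graph(layers, "eegnet", spec,
                  list(kind = "channels", n_channels = C, T = as.integer(T)))
}

# coerce supported batch containers to the engine's (M, T, B) array
model_input_array <- function(model, batch) {
  if (inherits(batch, "grid_dataset")) {
    d <- dim(batch$values)
    x <- aperm(batch$values, c(2, 3, 4, 1))
    dim(x) <- c(d[2] * d[3], d[4], d[1])
  } else if (inherits(batch, "epoched_dataset")) {
    if (model$input$kind == "grid")
      stop("shape mismatch: grid-input model needs map_to_grid() output",
           call. = FALSE)
    x <- aperm(batch$data, c(2, 3, 1))
  } else if (is.array(batch) && length(dim(batch)) == 3) {
    x <- batch
  } else {
    stop("unsupported batch type", call. = FALSE)
  }
  expect_M <- if (model$input$kind == "grid")
    model$input$C1 * model$input$C2 else model$input$n_channels
  if (dim(x)[1] != expect_M || dim(x)[2] != model$input$T)
    stop(sprintf("shape mismatch: model expects (%d units x %d samples), received (%d x %d)",
                 expect_M, model$input$T, dim(x)[1], dim(x)[2]), call. = FALSE)
  x
}

#' Forward pass: class probabilities
#'
#' Evaluation-mode forward pass (dropout off, batch-norm running
#' statistics); deterministic, rows sum to 1.
#'
#' @param model A `model_graph`.
#' @param batch A `grid_dataset`, [epoched_dataset()], or `(M, T, B)` array.
#' @return Matrix `B x n_classes` of class probabilities.
#' @export
forward <- function(model, batch) {
  stopifnot(inherits(model, "model_graph"))
  x <- model_input_array(model, batch)
  res <- graph_forward(model, x, mode = "eval")
  t(softmax_cols(res$logits))
}

#' @export
predict.model_graph <- function(object, batch, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- forward(object, batch)
  if (type == "prob") return(p)
  max.col(p, ties.method = "first") - 1L
}

#' Layer table of a model graph
#'
#' @param model A `model_graph`.
#' @return Tibble with one row per layer: kind, output shape, number of
#'   learnable parameters, and MACCs.
#' @export
describe_model <- function(model) {
  stopifnot(inherits(model, "model_graph"))
  tibble::tibble(
    layer = seq_along(model$layers),
    kind = vapply(model$layers, `[[`, "", "kind"),
    out_maps = vapply(model$layers, `[[`, 0L, "out_maps"),
    out_rows = vapply(model$layers, `[[`, 0L, "out_rows"),
    out_T = vapply(model$layers, function(l) as.integer(l$out_T), 0L),
    n_params = vapply(model$layers, function(l) as.integer(l$n_params), 0L),
    maccs = vapply(model$layers, function(l) as.numeric(layer_maccs(l)), 0)
  )
}

#' @export
print.model_graph <- function(x, ...) {
  cat(sprintf("<model_graph %s> %d layers, %d classes, %s parameters\n",
              x$kind, length(x$layers), x$n_classes,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}
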