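# Model cost accounting: learnable-parameter totals, multiply-accumulate
# (MACC) counts with an instrumented nested-loop oracle, and a documented
# memory-footprint estimate.
#
# Conventions: one MACC = one multiply(+add); biases, batch normalization,
# pooling, activations and softmax contribute zero; temporal convolutions
# use length-preserving padding. This convention reproduces the published
# EEGNet counts at three independent input shapes.

#' Count learnable parameters
#'
#' Sums kernels, biases (where the layer has one), and the two affine
#' batch-norm scalars per feature map.
#'
#' @param model A `model_graph`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "model_graph"))
  sum(vapply(model$layers, function(l) as.numeric(l$n_params), 0))
}

#' Count forward-pass MACCs analytically
#'
#' Convolution layers contribute (output elements) x (kernel taps x
#' per-group fan-in); the dense layer contributes inputs x outputs; all
#' other layers are free. Counts are per trial (batch-size invariant).
#'
#' @param model A `model_graph`.
#' @param input_shape Optional `c(M, T)` sanity check against the model's
#'   declared input.
#' @return Numeric MACC count.
#' @export
count_maccs <- function(model, input_shape = NULL) {
  stopifnot(inherits(model, "model_graph"))
  if (!is.null(input_shape)) {
    M <- if (model$input$kind == "grid") model$input$C1 * model$input$C2
         else model$input$n_channels
    assert_that(input_shape[1] == M && input_shape[2] == model$input$T,
                "input_shape disagrees with the model's declared input")
  }
  sum(vapply(model$layers, layer_maccs, 0))
}

#' Instrumented-forward MACC oracle
#'
#' Runs a naive nested-loop forward pass on a random input (batch 1),
#' incrementing a counter at every kernel/dense multiply. Slow by design;
#' intended as an independent check of [count_maccs()] on small graphs.
#'
#' @param model A `model_graph`.
#' @param seed Seed for the random probe input.
#' @return Numeric multiply count.
#' @export
maccs_oracle <- function(model, seed = 1L) {
  stopifnot(inherits(model, "model_graph"))
  set.seed(seed)
  M0 <- model$layers[[1]]$in_rows * model$layers[[1]]$in_maps
  x <- matrix(stats::rnorm(M0 * model$layers[[1]]$in_T), M0)   # (M, T)
  counter <- 0
  conv1d_same <- function(xrow, w) {
    K <- length(w)
    pp <- pad_lr(K)
    xp <- c(rep(0, pp[1]), xrow, rep(0, pp[2]))
    out <- numeric(length(xrow))
    for (t in seq_along(xrow)) {
      acc <- 0
      for (k in seq_len(K)) {
        acc <- acc + w[k] * xp[t + k - 1]
        counter <<- counter + 1
      }
      out[t] <- acc
    }
    out
  }
  for (layer in model$layers) {
    T <- dim(x)[2]
    x <- switch(layer$kind,
      conv_temporal = {
        C <- layer$in_rows; F1 <- layer$out_maps; W <- layer$params$W
        out <- array(0, c(C, F1, T))
        for (f in seq_len(F1)) for (c in seq_len(C))
          out[c, f, ] <- conv1d_same(x[c, ], W[f, ])
        matrix(out, nrow = C * F1)
      },
      conv_spatial_dw = {
        C <- layer$in_rows; F1 <- layer$in_maps; D <- layer$hyper$D
        W <- layer$params$W
        xr <- array(x, c(C, F1, T))
        out <- array(0, c(D, F1, T))
        for (f in seq_len(F1)) for (d in seq_len(D)) for (t in seq_len(T)) {
          acc <- 0
          for (c in seq_len(C)) {
            acc <- acc + W[d, c, f] * xr[c, f, t]
            counter <- counter + 1
          }
          out[d, f, t] <- acc
        }
        matrix(out, nrow = D * F1)
      },
      conv_full = {
        C <- layer$in_rows; F1 <- layer$out_maps; K <- layer$hyper$K
        W <- layer$params$W
        pp <- pad_lr(K)
        xp <- cbind(matrix(0, C, pp[1]), x, matrix(0, C, pp[2]))
        out <- matrix(0, F1, T)
        for (f in seq_len(F1)) for (t in seq_len(T)) {
          acc <- if (!is.null(layer$params$b)) layer$params$b[f] else 0
          for (k in seq_len(K)) for (c in seq_len(C)) {
            acc <- acc + W[f, c + (k - 1) * C] * xp[c, t + k - 1]
            counter <- counter + 1
          }
          out[f, t] <- acc
        }
        out
      },
      conv_dw_time = {
        out <- x
        for (m in seq_len(nrow(x))) out[m, ] <- conv1d_same(x[m, ], layer$params$W[m, ])
        out
      },
      conv_pointwise = {
        Fo <- layer$out_maps; Mi <- layer$in_maps; W <- layer$params$W
        out <- matrix(0, Fo, T)
        for (f in seq_len(Fo)) for (t in seq_len(T)) {
          acc <- if (!is.null(layer$params$b)) layer$params$b[f] else 0
          for (m in seq_len(Mi)) {
            acc <- acc + W[f, m] * x[m, t]
            counter <- counter + 1
          }
          out[f, t] <- acc
        }
        out
      },
      batchnorm = x,                       # excluded from the convention
      elu = ifelse(x > 0, x, exp(x) - 1),
      pool_max = {
        p <- layer$hyper$p; T2 <- T %/% p
        out <- matrix(0, nrow(x), T2)
        for (s in seq_len(T2)) out[, s] <- apply(x[, ((s - 1) * p + 1):(s * p), drop = FALSE], 1, max)
        out
      },
      pool_avg = {
        p <- layer$hyper$p; T2 <- T %/% p
        out <- matrix(0, nrow(x), T2)
        for (s in seq_len(T2)) out[, s] <- rowMeans(x[, ((s - 1) * p + 1):(s * p), drop = FALSE])
        out
      },
      dropout = x,
      dense = {
        W <- layer$params$W; N <- layer$out_maps
        xv <- as.numeric(x)
        out <- numeric(N)
        for (n in seq_len(N)) {
          acc <- layer$params$b[n]
          for (j in seq_along(xv)) {
            acc <- acc + W[n, j] * xv[j]
            counter <- counter + 1
          }
          out[n] <- acc
        }
        matrix(out, ncol = 1)
      },
      stop("oracle: unknown layer ", layer$kind))
  }
  counter
}

#' Estimate the memory footprint of a model
#'
#' Reported estimate = parameter bytes + peak activation bytes (the largest
#' input+output pair of any layer at batch 1) + input bytes, at
#' `bytes_per_value` each. This is an explicit convention
#' (`"params+peak_act+input, batch1, float32"`), not a reproduction of any
#' particular framework's accounting.
#'
#' @param model A `model_graph`.
#' @param bytes_per_value Bytes per stored value (default 4, float32).
#' @return Numeric byte estimate with attribute `"convention"`.
#' @export
estimate_memory <- function(model, bytes_per_value = 4) {
  stopifnot(inherits(model, "model_graph"))
  elems <- function(rows, maps, T) rows * maps * T
  act <- vapply(model$layers, function(l)
    elems(l$in_rows, l$in_maps, l$in_T) + elems(l$out_rows, l$out_maps, l$out_T), 0)
  l1 <- model$layers[[1]]
  input_elems <- elems(l1$in_rows, l1$in_maps, l1$in_T)
  out <- (count_parameters(model) + max(act) + input_elems) * bytes_per_value
  attr(out, "convention") <- "params+peak_act+input, batch1, float32"
  out
}

#' Full cost report for a model
#'
#' @param model A `model_graph`.
#' @return A `cost_report`: tibble of the per-layer breakdown with totals
#'   (`n_parameters`, `n_maccs`, `memory_bytes`) as attributes.
#' @export
cost_report <- function(model) {
  br <- describe_model(model)
  structure(br, class = c("cost_report", class(br)),
            n_parameters = count_parameters(model),
            n_maccs = count_maccs(model),
            memory_bytes = as.numeric(estimate_memory(model)),
            kind = model$kind)
}

#' @export
print.cost_report <- function(x, ...) {
  cat(sprintf("<cost_report %s> %s parameters, %.4g M MACCs, %.3g MB (est.)\n",
              attr(x, "kind"), format(attr(x, "n_parameters"), big.mark = ","),
              attr(x, "n_maccs") / 1e6, attr(x, "memory_bytes") / 2^20))
  NextMethod()
}
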