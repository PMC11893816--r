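# Layer-graph engine.
#
# Activations are 3-D arrays (M, T, B): M units per time step (rows within
# maps, rows fastest), T time samples, B trials in the batch. Every layer
# records its shapes, learnable parameters, and MACC cost, and implements a
# forward pass (train/eval) and an exact backward pass, so the same graph
# object serves training, inference, and cost accounting.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

new_layer <- function(kind, in_rows, in_maps, in_T, out_rows, out_maps, out_T,
                      params = list(), buffers = list(), hyper = list()) {
  n_params <- sum(vapply(params, length, 0L))
  list(kind = kind, in_rows = in_rows, in_maps = in_maps, in_T = in_T,
       out_rows = out_rows, out_maps = out_maps, out_T = out_T,
       params = params, buffers = buffers, hyper = hyper, n_params = n_params)
}

init_uniform <- function(dims, fan_in) {
  lim <- sqrt(1 / fan_in)
  array(stats::runif(prod(dims), -lim, lim), dims)
}

# "same" temporal padding (asymmetric for even kernels)
pad_lr <- function(K) {
  pl <- (K - 1L) %/% 2L
  c(pl, K - 1L - pl)
}

pad_time <- function(x, pl, pr) {
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + pl + pr, d[3]))
  out[, (pl + 1):(pl + d[2]), ] <- x
  out
}

# ---- layer constructors ---------------------------------------------------

layer_conv_temporal <- function(C, F1, K, T) {
  new_layer("conv_temporal", in_rows = C, in_maps = 1L, in_T = T,
            out_rows = C, out_maps = F1, out_T = T,
            params = list(W = init_uniform(c(F1, K), K)),
            hyper = list(K = K))
}

layer_conv_spatial_dw <- function(C, F1, D, T) {
  new_layer("conv_spatial_dw", in_rows = C, in_maps = F1, in_T = T,
            out_rows = 1L, out_maps = D * F1, out_T = T,
            params = list(W = init_uniform(c(D, C, F1), C)),
            hyper = list(D = D))
}

layer_conv_full <- function(C, F, K, T, bias = TRUE) {
  params <- list(W = init_uniform(c(F, C * K), C * K))
  if (bias) params$b <- numeric(F)
  new_layer("conv_full", in_rows = C, in_maps = 1L, in_T = T,
            out_rows = 1L, out_maps = F, out_T = T,
            params = params, hyper = list(K = K, C = C, bias = bias))
}

layer_conv_dw_time <- function(M, K, T) {
  new_layer("conv_dw_time", in_rows = 1L, in_maps = M, in_T = T,
            out_rows = 1L, out_maps = M, out_T = T,
            params = list(W = init_uniform(c(M, K), K)),
            hyper = list(K = K))
}

layer_conv_pointwise <- function(M_in, F_out, T, bias = FALSE) {
  params <- list(W = init_uniform(c(F_out, M_in), M_in))
  if (bias) params$b <- numeric(F_out)
  new_layer("conv_pointwise", in_rows = 1L, in_maps = M_in, in_T = T,
            out_rows = 1L, out_maps = F_out, out_T = T,
            params = params, hyper = list(bias = bias))
}

layer_batchnorm <- function(rows, maps, T) {
  new_layer("batchnorm", in_rows = rows, in_maps = maps, in_T = T,
            out_rows = rows, out_maps = maps, out_T = T,
            params = list(gamma = rep(1, maps), beta = rep(0, maps)),
            buffers = list(run_mean = rep(0, maps), run_var = rep(1, maps)))
}

layer_elu <- function(rows, maps, T) {
  new_layer("elu", rows, maps, T, rows, maps, T)
}

layer_pool <- function(rows, maps, T, p, type = c("max", "avg")) {
  type <- match.arg(type)
  new_layer(paste0("pool_", type), rows, maps, T, rows, maps, T %/% p,
            hyper = list(p = as.integer(p)))
}

layer_dropout <- function(rows, maps, T, p_drop = 0.5) {
  new_layer("dropout", rows, maps, T, rows, maps, T,
            hyper = list(p_drop = p_drop))
}

layer_dense <- function(rows, maps, T, N) {
  M <- rows * maps
  new_layer("dense", in_rows = rows, in_maps = maps, in_T = T,
            out_rows = 1L, out_maps = N, out_T = 1L,
            params = list(W = init_uniform(c(N, M * T), M * T), b = numeric(N)),
            hyper = list(N = N))
}

# analytic MACC count of one layer (multiply-accumulates; biases, batch
# norm, pooling, activations and softmax are free by convention)
layer_maccs <- function(layer) {
  with(layer, switch(kind,
    conv_temporal   = out_maps * out_rows * out_T * hyper$K,
    conv_spatial_dw = out_maps * out_T * in_rows,
    conv_full       = out_maps * out_T * (in_rows * hyper$K),
    conv_dw_time    = out_maps * out_T * hyper$K,
    conv_pointwise  = out_maps * out_T * in_maps,
    dense           = out_maps * in_rows * in_maps * in_T,
    0))
}

# ---- forward --------------------------------------------------------------

fwd_layer <- function(layer, x, mode) {
  M <- layer$in_rows * layer$in_maps
  T <- dim(x)[2]; B <- dim(x)[3]
  switch(layer$kind,
    conv_temporal = {
      K <- layer$hyper$K; C <- layer$in_rows; F1 <- layer$out_maps
      pp <- pad_lr(K)
      Xpad <- pad_time(x, pp[1], pp[2])
      W <- layer$params$W
      OutM <- matrix(0, F1, C * T * B)
      for (k in seq_len(K)) {
        xv <- as.numeric(Xpad[, k:(k + T - 1), , drop = FALSE])
        OutM <- OutM + W[, k, drop = FALSE] %*% matrix(xv, nrow = 1)
      }
      out <- aperm(array(OutM, c(F1, C, T, B)), c(2, 1, 3, 4))
      dim(out) <- c(C * F1, T, B)
      list(out = out, cache = list(Xpad = Xpad))
    },
    conv_spatial_dw = {
      C <- layer$in_rows; F1 <- layer$in_maps
      W <- layer$params$W; D <- layer$hyper$D
      xr <- array(x, c(C, F1, T, B))
      out <- array(0, c(D, F1, T, B))
      for (f in seq_len(F1))
        out[, f, , ] <- W[, , f] %*% matrix(xr[, f, , ], nrow = C)
      dim(out) <- c(D * F1, T, B)
      list(out = out, cache = list(xr = xr))
    },
    conv_full = {
      K <- layer$hyper$K; C <- layer$in_rows; F1 <- layer$out_maps
      pp <- pad_lr(K)
      Xpad <- pad_time(x, pp[1], pp[2])
      Xcol <- matrix(0, C * K, T * B)
      for (k in seq_len(K))
        Xcol[((k - 1) * C + 1):(k * C), ] <-
          matrix(Xpad[, k:(k + T - 1), , drop = FALSE], nrow = C)
      OutM <- layer$params$W %*% Xcol
      if (!is.null(layer$params$b)) OutM <- OutM + layer$params$b
      list(out = array(OutM, c(F1, T, B)), cache = list(Xcol = Xcol, Tp = dim(Xpad)[2]))
    },
    conv_dw_time = {
      K <- layer$hyper$K
      pp <- pad_lr(K)
      Xpad <- pad_time(x, pp[1], pp[2])
      W <- layer$params$W
      out <- array(0, c(M, T, B))
      for (k in seq_len(K))
        out <- out + W[, k] * Xpad[, k:(k + T - 1), , drop = FALSE]
      list(out = out, cache = list(Xpad = Xpad))
    },
    conv_pointwise = {
      OutM <- layer$params$W %*% matrix(x, nrow = M)
      if (!is.null(layer$params$b)) OutM <- OutM + layer$params$b
      list(out = array(OutM, c(layer$out_maps, T, B)), cache = list(xm = matrix(x, nrow = M)))
    },
    batchnorm = {
      rows <- layer$in_rows; maps <- layer$in_maps
      # work in (maps, N) orientation (maps fastest) so per-map statistics
      # vectorize by recycling; rows > 1 needs a permutation first
      if (rows == 1L) {
        xm <- matrix(x, nrow = maps)
      } else {
        xm <- matrix(aperm(array(x, c(rows, maps, T, B)), c(2, 1, 3, 4)),
                     nrow = maps)
      }
      if (mode == "train") {
        mu <- rowMeans(xm)
        v <- rowMeans(xm * xm) - mu^2
        layer$buffers$run_mean <- (1 - BN_MOMENTUM) * layer$buffers$run_mean + BN_MOMENTUM * mu
        layer$buffers$run_var <- (1 - BN_MOMENTUM) * layer$buffers$run_var + BN_MOMENTUM * v
      } else {
        mu <- layer$buffers$run_mean
        v <- layer$buffers$run_var
      }
      inv_sd <- 1 / sqrt(v + BN_EPS)
      xhat <- (xm - mu) * inv_sd
      ym <- xhat * layer$params$gamma + layer$params$beta
      if (rows == 1L) {
        out <- array(ym, c(maps, T, B))
      } else {
        out <- aperm(array(ym, c(maps, rows, T, B)), c(2, 1, 3, 4))
        dim(out) <- c(rows * maps, T, B)
      }
      list(out = out,
           cache = list(xhat = xhat, inv_sd = inv_sd,
                        shape = c(rows, maps, T, B), batch_stats = mode == "train"),
           layer = layer)
    },
    elu = {
      neg <- x < 0
      out <- x
      out[neg] <- exp(pmin(x[neg], 50)) - 1
      list(out = out, cache = list(out = out, neg = neg))
    },
    pool_max = {
      p <- layer$hyper$p; T2 <- T %/% p
      xr <- array(x[, seq_len(T2 * p), , drop = FALSE], c(M, p, T2, B))
      best <- xr[, 1, , , drop = FALSE]
      argj <- array(1L, dim(best))
      if (p > 1) for (j in 2:p) {
        cand <- xr[, j, , , drop = FALSE]
        upd <- cand > best
        best[upd] <- cand[upd]
        argj[upd] <- j
      }
      out <- array(best, c(M, T2, B))
      # linear indices of the winners inside the (M, p, T2, B) layout,
      # ordered like the flattened (M, T2, B) output
      off <- as.vector(outer((seq_len(T2) - 1) * M * p,
                             (seq_len(B) - 1) * M * p * T2, `+`))
      base <- rep(seq_len(M), times = T2 * B) + rep(off, each = M)
      win <- base + (as.vector(argj) - 1L) * M
      list(out = out, cache = list(win = win, p = p, T_in = T))
    },
    pool_avg = {
      p <- layer$hyper$p; T2 <- T %/% p
      xr <- array(x[, seq_len(T2 * p), , drop = FALSE], c(M, p, T2, B))
      out <- array(0, c(M, T2, B))
      for (j in seq_len(p)) out <- out + array(xr[, j, , , drop = FALSE], c(M, T2, B))
      list(out = out / p, cache = list(p = p, T_in = T))
    },
    dropout = {
      if (mode == "train") {
        p <- layer$hyper$p_drop
        mask <- array((stats::runif(length(x)) >= p) / (1 - p), dim(x))
        list(out = x * mask, cache = list(mask = mask))
      } else {
        list(out = x, cache = list(mask = NULL))
      }
    },
    dense = {
      Xm <- matrix(x, nrow = M * T)
      out <- layer$params$W %*% Xm + layer$params$b
      list(out = array(out, c(layer$out_maps, 1L, B)), cache = list(Xm = Xm))
    },
    stop("unknown layer kind: ", layer$kind)
  )
}

# ---- backward -------------------------------------------------------------

bwd_layer <- function(layer, g, cache) {
  M <- layer$in_rows * layer$in_maps
  switch(layer$kind,
    conv_temporal = {
      K <- layer$hyper$K; C <- layer$in_rows; F1 <- layer$out_maps
      Xpad <- cache$Xpad
      T <- layer$in_T; B <- dim(g)[3]
      gr <- array(g, c(C, F1, T, B))
      GM <- matrix(aperm(gr, c(2, 1, 3, 4)), nrow = F1)   # (F1, C*T*B)
      W <- layer$params$W
      gW <- matrix(0, F1, K)
      gXpad <- array(0, dim(Xpad))
      for (k in seq_len(K)) {
        xv <- as.numeric(Xpad[, k:(k + T - 1), , drop = FALSE])
        gW[, k] <- GM %*% xv
        gXpad[, k:(k + T - 1), ] <- gXpad[, k:(k + T - 1), , drop = FALSE] +
          array(crossprod(W[, k, drop = FALSE], GM), c(C, T, B))
      }
      pp <- pad_lr(K)
      list(gin = gXpad[, (pp[1] + 1):(pp[1] + T), , drop = FALSE],
           grads = list(W = gW))
    },
    conv_spatial_dw = {
      C <- layer$in_rows; F1 <- layer$in_maps; D <- layer$hyper$D
      T <- layer$in_T; B <- dim(g)[3]
      gr <- array(g, c(D, F1, T, B))
      W <- layer$params$W
      gW <- array(0, dim(W))
      gx <- array(0, c(C, F1, T, B))
      for (f in seq_len(F1)) {
        Gf <- matrix(gr[, f, , ], nrow = D)
        Xf <- matrix(cache$xr[, f, , ], nrow = C)
        gW[, , f] <- Gf %*% t(Xf)
        gx[, f, , ] <- crossprod(W[, , f], Gf)
      }
      dim(gx) <- c(C * F1, T, B)
      list(gin = gx, grads = list(W = gW))
    },
    conv_full = {
      K <- layer$hyper$K; C <- layer$in_rows
      T <- layer$in_T; B <- dim(g)[3]
      GM <- matrix(g, nrow = layer$out_maps)
      gW <- GM %*% t(cache$Xcol)
      grads <- list(W = gW)
      if (!is.null(layer$params$b)) grads$b <- rowSums(GM)
      gXcol <- crossprod(layer$params$W, GM)
      gXpad <- array(0, c(C, cache$Tp, B))
      for (k in seq_len(K))
        gXpad[, k:(k + T - 1), ] <- gXpad[, k:(k + T - 1), , drop = FALSE] +
          array(gXcol[((k - 1) * C + 1):(k * C), ], c(C, T, B))
      pp <- pad_lr(K)
      list(gin = gXpad[, (pp[1] + 1):(pp[1] + T), , drop = FALSE], grads = grads)
    },
    conv_dw_time = {
      K <- layer$hyper$K
      T <- layer$in_T; B <- dim(g)[3]
      Xpad <- cache$Xpad
      W <- layer$params$W
      gW <- matrix(0, M, K)
      gXpad <- array(0, dim(Xpad))
      for (k in seq_len(K)) {
        xs <- Xpad[, k:(k + T - 1), , drop = FALSE]
        gW[, k] <- rowSums(matrix(g * xs, nrow = M))
        gXpad[, k:(k + T - 1), ] <- gXpad[, k:(k + T - 1), , drop = FALSE] + W[, k] * g
      }
      pp <- pad_lr(K)
      list(gin = gXpad[, (pp[1] + 1):(pp[1] + T), , drop = FALSE],
           grads = list(W = gW))
    },
    conv_pointwise = {
      GM <- matrix(g, nrow = layer$out_maps)
      grads <- list(W = GM %*% t(cache$xm))
      if (!is.null(layer$params$b)) grads$b <- rowSums(GM)
      gin <- crossprod(layer$params$W, GM)
      list(gin = array(gin, c(M, layer$in_T, dim(g)[3])), grads = grads)
    },
    batchnorm = {
      sh <- cache$shape  # rows, maps, T, B
      rows <- sh[1]; maps <- sh[2]; T <- sh[3]; B <- sh[4]
      if (rows == 1L) {
        gm <- matrix(g, nrow = maps)
      } else {
        gm <- matrix(aperm(array(g, c(rows, maps, T, B)), c(2, 1, 3, 4)),
                     nrow = maps)
      }
      xhat <- cache$xhat
      gGamma <- rowSums(gm * xhat)
      gBeta <- rowSums(gm)
      coef <- layer$params$gamma * cache$inv_sd
      if (isTRUE(cache$batch_stats)) {
        gx <- coef * (gm - rowMeans(gm) - xhat * rowMeans(gm * xhat))
      } else {
        gx <- coef * gm                 # running stats are constants
      }
      if (rows == 1L) {
        gin <- array(gx, c(maps, T, B))
      } else {
        gin <- aperm(array(gx, c(maps, rows, T, B)), c(2, 1, 3, 4))
        dim(gin) <- c(rows * maps, T, B)
      }
      list(gin = gin, grads = list(gamma = gGamma, beta = gBeta))
    },
    elu = {
      d <- g
      d[cache$neg] <- g[cache$neg] * (cache$out[cache$neg] + 1)
      list(gin = d, grads = list())
    },
    pool_max = {
      p <- cache$p; T_in <- cache$T_in
      T2 <- dim(g)[2]; B <- dim(g)[3]
      gxr <- numeric(M * p * T2 * B)
      gxr[cache$win] <- g                 # scatter to the argmax positions
      gin <- array(0, c(M, T_in, B))
      gin[, seq_len(T2 * p), ] <- array(gxr, c(M, T2 * p, B))
      list(gin = gin, grads = list())
    },
    pool_avg = {
      p <- cache$p; T_in <- cache$T_in
      T2 <- dim(g)[2]; B <- dim(g)[3]
      gxr <- array(0, c(M, p, T2, B))
      for (j in seq_len(p)) gxr[, j, , ] <- g / p
      gin <- array(0, c(M, T_in, B))
      gin[, seq_len(T2 * p), ] <- array(gxr, c(M, T2 * p, B))
      list(gin = gin, grads = list())
    },
    dropout = {
      if (is.null(cache$mask)) list(gin = g, grads = list())
      else list(gin = g * cache$mask, grads = list())
    },
    dense = {
      GM <- matrix(g, nrow = layer$out_maps)
      gW <- GM %*% t(cache$Xm)
      gb <- rowSums(GM)
      gin <- crossprod(layer$params$W, GM)
      list(gin = array(gin, c(M, layer$in_T, dim(g)[3])),
           grads = list(W = gW, b = gb))
    },
    stop("unknown layer kind: ", layer$kind)
  )
}

# full forward pass; returns logits and per-layer caches, and (train mode)
# the model with updated batch-norm running statistics
graph_forward <- function(model, x, mode = "eval") {
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    res <- fwd_layer(model$layers[[i]], x, mode)
    if (!is.null(res$layer)) model$layers[[i]] <- res$layer
    caches[[i]] <- res$cache
    x <- res$out
  }
  list(logits = matrix(x, nrow = model$n_classes), caches = caches, model = model)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), `/`)
}

# mean cross-entropy loss + gradient wrt logits for 0-based labels
softmax_xent <- function(logits, labels) {
  p <- softmax_cols(logits)
  B <- ncol(p)
  idx <- cbind(labels + 1L, seq_len(B))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = loss, grad = g / B, probs = p)
}

graph_backward <- function(model, caches, g_logits) {
  n <- length(model$layers)
  g <- array(g_logits, c(model$n_classes, 1L, ncol(g_logits)))
  grads <- vector("list", n)
  for (i in rev(seq_len(n))) {
    res <- bwd_layer(model$layers[[i]], g, caches[[i]])
    grads[[i]] <- res$grads
    g <- res$gin
  }
  grads
}
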