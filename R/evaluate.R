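# Within-subject evaluation: stratified 5-fold cross-validation against a
# fixed held-out test set, Cohen's kappa, and the paired Wilcoxon
# signed-rank comparison used between models.

data_subset <- function(data, idx) {
  if (inherits(data, "grid_dataset")) {
    out <- data
    out$values <- data$values[idx, , , , drop = FALSE]
    out$labels <- data$labels[idx]
    out
  } else if (inherits(data, "epoched_dataset")) {
    epochs_subset(data, idx)
  } else stop("unsupported dataset type", call. = FALSE)
}

data_n <- function(data) {
  if (inherits(data, "grid_dataset")) dim(data$values)[1] else dim(data$data)[1]
}

# stratified fold assignment: shuffle within class, deal into n_folds
# blocks, preserving class proportions within +-1 trial
stratified_folds <- function(labels, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in sort(unique(labels))) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Construct a cross-validation result
#'
#' @param fold_acc Per-fold test accuracies.
#' @param confusions List of per-fold confusion matrices (true x predicted),
#'   used for the kappa score; may be `NULL`.
#' @param meta Optional named list describing the configuration.
#' @return A `cv_result` with fields `fold_acc`, `mean`, `min`, `max`,
#'   `std`, `kappa`, `confusions`.
#' @export
cv_result <- function(fold_acc, confusions = NULL, meta = list()) {
  assert_that(all(fold_acc >= 0 & fold_acc <= 1), "accuracies must lie in [0,1]")
  kap <- if (!is.null(confusions))
    mean(vapply(confusions, cohen_kappa, 0)) else NA_real_
  structure(list(fold_acc = as.numeric(fold_acc), mean = mean(fold_acc),
                 min = min(fold_acc), max = max(fold_acc),
                 std = stats::sd(fold_acc), kappa = kap,
                 confusions = confusions, meta = meta),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> mean %.4f (min %.4f, max %.4f, sd %.4f), kappa %.4f [%d folds]\n",
              x$mean, x$min, x$max, x$std, x$kappa, length(x$fold_acc)))
  invisible(x)
}

confusion_matrix <- function(true, pred, n_classes) {
  m <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(true)) m[true[i] + 1L, pred[i] + 1L] <- m[true[i] + 1L, pred[i] + 1L] + 1L
  m
}

#' 5-fold cross-validation against a fixed test set
#'
#' The training pool is split into 5 stratified folds; each rotation uses
#' 4 folds (80%) for training and 1 fold (20%) for validation-based early
#' stopping, and the resulting model is evaluated once on the fixed
#' held-out test set. The result records the min/max/mean/std of the five
#' test accuracies and the per-fold-averaged Cohen's kappa.
#'
#' @param train_pool Training `grid_dataset` or [epoched_dataset()]
#'   (>= `n_folds` trials per class).
#' @param test Fixed test set of the same type.
#' @param spec Model specification ([proposed_3dcnn_spec()] or
#'   [eegnet_spec()]).
#' @param cfg A [train_config()]; fold seeds are derived from its
#'   `shuffle_seed`.
#' @param n_folds Number of folds (5 in the reference protocol).
#' @return A [cv_result()].
#' @export
crossval_5fold <- function(train_pool, test, spec, cfg = train_config(),
                           n_folds = 5L) {
  labels <- data_labels(train_pool)
  tab <- table(labels)
  if (any(tab < n_folds))
    stop("stratification error: class(es) with fewer trials than folds: ",
         paste(names(tab)[tab < n_folds], collapse = ", "), call. = FALSE)
  fold <- stratified_folds(labels, n_folds, derive_seed(cfg$shuffle_seed, "folds"))
  ytest <- data_labels(test)
  n_classes <- max(c(labels, ytest)) + 1L
  accs <- numeric(n_folds)
  confs <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    cfg_f <- cfg
    cfg_f$shuffle_seed <- derive_seed(cfg$shuffle_seed, paste0("fold", f))
    fit <- train_model(data_subset(train_pool, which(fold != f)),
                       data_subset(train_pool, which(fold == f)),
                       spec, cfg_f)
    pred <- predict(fit$model, test)
    accs[f] <- mean(pred == ytest)
    confs[[f]] <- confusion_matrix(ytest, pred, n_classes)
  }
  cv_result(accs, confs,
            meta = list(n_folds = n_folds, seed = cfg$shuffle_seed,
                        spec = class(spec)[1]))
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with `p_o` the
#' observed agreement (diagonal mass) and `p_e` the chance agreement
#' expected from the row/column marginals.
#'
#' @param confusion Square non-negative matrix (true x predicted) with a
#'   positive total.
#' @return Kappa in `[-1, 1]`; `NaN` with a warning when the marginals are
#'   degenerate (`p_e = 1`).
#' @export
cohen_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  assert_that(nrow(confusion) == ncol(confusion) && all(confusion >= 0) &&
                sum(confusion) > 0,
              "confusion must be square, non-negative, with positive total")
  n <- sum(confusion)
  p_o <- sum(diag(confusion)) / n
  p_e <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (1 - p_e < .Machine$double.eps) {
    warning("degenerate marginals: chance agreement is 1, kappa undefined")
    return(NaN)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired samples, with the exact signed-rank
#' distribution when there are at most 25 nonzero differences and no ties,
#' and the normal approximation with tie correction otherwise.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @return List with `p_value`, `statistic` (V), `n` (nonzero pairs) and
#'   `method`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  assert_that(length(a) == length(b), "a and b must be paired (equal length)")
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all differences zero: test undefined")
    return(list(p_value = NA_real_, statistic = NA_real_, n = 0L,
                method = "undefined"))
  }
  assert_that(length(d) >= 5, "need at least 5 nonzero differences")
  ties <- anyDuplicated(abs(d)) > 0
  exact <- length(d) <= 25 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, paired = TRUE, exact = exact, correct = FALSE))
  list(p_value = unname(wt$p.value), statistic = unname(wt$statistic),
       n = length(d),
       method = if (exact) "exact" else "normal approximation (tie-corrected)")
}
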