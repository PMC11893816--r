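# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) {
  tibble::tibble(fold = seq_along(x$fold_acc), accuracy = x$fold_acc)
}

#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(mean = x$mean, min = x$min, max = x$max, std = x$std,
                 kappa = x$kappa, n_folds = length(x$fold_acc))
}

#' @method tidy trained_model
#' @export
tidy.trained_model <- function(x, ...) x$history

#' @method glance trained_model
#' @export
glance.trained_model <- function(x, ...) {
  tibble::tibble(best_epoch = x$best_epoch,
                 best_val_loss = min(x$history$val_loss),
                 best_val_acc = x$history$val_acc[which.min(x$history$val_loss)],
                 epochs_run = nrow(x$history),
                 n_parameters = count_parameters(x$model))
}

#' @method tidy cost_report
#' @export
tidy.cost_report <- function(x, ...) tibble::as_tibble(unclass(x))

#' @method glance cost_report
#' @export
glance.cost_report <- function(x, ...) {
  tibble::tibble(n_parameters = attr(x, "n_parameters"),
                 n_maccs = attr(x, "n_maccs"),
                 memory_bytes = attr(x, "memory_bytes"),
                 parameters_k = attr(x, "n_parameters") / 1e3,
                 maccs_M = attr(x, "n_maccs") / 1e6)
}

#' @method tidy channel_selection_trace
#' @export
tidy.channel_selection_trace <- function(x, ...) {
  dplyr::select(x$steps, -dplyr::any_of(c("candidates", "cv")))
}

#' @method glance channel_selection_trace
#' @export
glance.channel_selection_trace <- function(x, ...) {
  tibble::tibble(final_channels = paste(x$final_channels, collapse = ","),
                 n_final = length(x$final_channels),
                 n_steps = nrow(x$steps),
                 n_evaluations = x$n_evaluations,
                 termination = x$termination)
}

#' @method tidy erd_map
#' @export
tidy.erd_map <- function(x, ...) tibble::as_tibble(unclass(x))

#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean, linetype = 2) +
    ggplot2::labs(x = "fold", y = "test accuracy",
                  title = sprintf("5-fold CV: mean %.3f (min %.3f, max %.3f)",
                                  object$mean, object$min, object$max)) +
    ggplot2::theme_minimal()
}

#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, ...) {
  xvar <- if (attr(object, "sweep") == "window") "window_len_s" else "subsample_n"
  base <- attr(object, "baseline")
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[xvar]], y = .data$mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                           width = 0.1) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$maintained), size = 2) +
    ggplot2::geom_hline(yintercept = base$min, colour = "red") +
    ggplot2::labs(x = xvar, y = "classification accuracy",
                  colour = "maintained") +
    ggplot2::theme_minimal()
}

#' @method autoplot pareto_front
#' @export
autoplot.pareto_front <- function(object, ...) {
  pts <- attr(object, "points")
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$n_parameters, y = .data$accuracy)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_step(data = as.data.frame(object), colour = "steelblue",
                       direction = "hv") +
    ggplot2::geom_point(data = as.data.frame(object), colour = "steelblue",
                        size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "#parameters", y = "mean classification accuracy") +
    ggplot2::theme_minimal()
}

#' @method autoplot erd_map
#' @export
autoplot.erd_map <- function(object, layout = NULL, ...) {
  if (is.null(layout)) {
    mont <- attr(object, "montage")
    df <- dplyr::left_join(tibble::as_tibble(unclass(object)),
                           tibble::as_tibble(unclass(mont)), by = "channel")
  } else {
    cm <- layout$cell_map
    df <- dplyr::left_join(tibble::as_tibble(unclass(object)), cm, by = "channel")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$erd_pct)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$channel), size = 3) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0) +
    ggplot2::labs(fill = "ERD %", x = NULL, y = NULL,
                  title = "ERD/ERS topography (front at top)") +
    ggplot2::theme_void()
}

#' @importFrom rlang .data
NULL
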