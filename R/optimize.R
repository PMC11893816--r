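# Measurement-condition optimization: the staged channel-elimination
# search, sample-window and subsampling sweeps, the accuracy-maintenance
# predicate, and Pareto-front construction.

#' Accuracy-maintenance predicate
#'
#' A candidate configuration "maintains" accuracy when the maximum of its
#' 5-fold cross-validation test accuracies reaches at least the minimum of
#' the baseline's (the full-montage, full-window reference). The predicate
#' is monotone: improving any candidate fold accuracy can never flip it
#' from true to false.
#'
#' @param candidate,baseline [cv_result()] objects.
#' @return Logical.
#' @export
accuracy_maintained <- function(candidate, baseline) {
  stopifnot(inherits(candidate, "cv_result"), inherits(baseline, "cv_result"))
  candidate$max >= baseline$min
}

#' Channel-selection protocol options
#'
#' @param top_k,bottom_k How many of the best/worst subsets enter the
#'   channel-frequency tally in the combinatorial phase (10 in the
#'   reference procedure).
#' @param tie_expand Expanded list size used when the tally ties (15).
#' @param candidate_reps Cross-validation repetitions per candidate subset
#'   in the leave-one-out phase.
#' @param confirm_reps Repetitions used to confirm the chosen subset.
#' @param min_channels Smallest subset size to consider.
#' @param max_evals Optional budget on subset evaluations; exceeding it
#'   returns a partial trace with an explicit termination reason.
#' @return A list of class `selection_protocol`.
#' @export
selection_protocol <- function(top_k = 10, bottom_k = 10, tie_expand = 15,
                               candidate_reps = 2, confirm_reps = 10,
                               min_channels = 1, max_evals = Inf) {
  assert_that(top_k >= 1 && bottom_k >= 1, "top_k and bottom_k must be >= 1")
  structure(list(top_k = top_k, bottom_k = bottom_k, tie_expand = tie_expand,
                 candidate_reps = candidate_reps, confirm_reps = confirm_reps,
                 min_channels = min_channels, max_evals = max_evals),
            class = "selection_protocol")
}

as_subject_list <- function(data) {
  if (!is.null(data$train)) list(data) else data
}

# evaluate one channel subset for every subject; returns list of cv_results
eval_channel_subset <- function(subjects, channels, spec, cfg, layout_fn,
                                reps = 1, seed_tag = "") {
  lapply(seq_along(subjects), function(s) {
    tr <- epochs_select_channels(subjects[[s]]$train, channels)
    te <- epochs_select_channels(subjects[[s]]$test, channels)
    if (inherits(spec, "proposed_3dcnn_spec")) {
      lay <- layout_fn(tr$channels)
      tr <- map_to_grid(tr, lay)
      te <- map_to_grid(te, lay)
    }
    accs <- c(); confs <- list()
    for (r in seq_len(reps)) {
      cfg_r <- cfg
      cfg_r$shuffle_seed <- derive_seed(
        cfg$shuffle_seed, paste0(seed_tag, "|s", s, "|", paste(channels, collapse = ","), "|r", r))
      cv <- crossval_5fold(tr, te, spec, cfg_r)
      accs <- c(accs, cv$fold_acc)
      confs <- c(confs, cv$confusions)
    }
    cv_result(accs, confs, meta = list(channels = channels, subject = s))
  })
}

mean_acc <- function(cvs) mean(vapply(cvs, `[[`, 0, "mean"))

#' Staged channel-elimination search
#'
#' Reproduces the two-phase electrode reduction procedure. While more than
#' 10 channels remain, every subset of size n-2 is evaluated by stratified
#' 5-fold cross-validation; the channels appearing most often in the
#' `bottom_k` worst subsets and least often in the `top_k` best subsets
#' (score = bottom-count minus top-count) are the two removed, with tally
#' ties broken by expanding the lists to `tie_expand` and finally by the
#' best-accuracy subset. At 10 channels or fewer, all leave-one-out subsets
#' are evaluated with `candidate_reps` repetitions, the best is confirmed
#' with `confirm_reps` repetitions, and one channel is removed per step.
#' The search descends while the accuracy-maintenance predicate holds for
#' every subject against the full-montage baseline, and returns the full
#' decision record.
#'
#' @param data One subject's `list(train =, test =)` of
#'   [epoched_dataset()]s (already preprocessed), or a list of such lists
#'   for multiple subjects.
#' @param spec Model specification used for every evaluation.
#' @param protocol A [selection_protocol()].
#' @param cfg A [train_config()] (use [screening_config()] for desk-scale
#'   searches).
#' @param layout_fn Maps a channel vector to the [grid_layout()] used by
#'   the 3D-CNN (default: single-row layout).
#' @param eval_fn Evaluation backend `function(channels, reps, seed_tag)`
#'   returning one [cv_result()] per subject. Defaults to the full
#'   cross-validated model training; injectable for protocol-level testing
#'   and for custom screening classifiers.
#' @return A `channel_selection_trace`: list with `final_channels`,
#'   `baseline` (per-subject [cv_result()]s), `steps` (tibble, one row per
#'   elimination step with candidate records), `termination`.
#' @export
channel_elimination_search <- function(data, spec, protocol = selection_protocol(),
                                       cfg = screening_config(),
                                       layout_fn = layout_row,
                                       eval_fn = NULL) {
  subjects <- as_subject_list(data)
  channels <- subjects[[1]]$train$channels
  assert_that(length(channels) >= 3, "need at least 3 channels")
  if (is.null(eval_fn))
    eval_fn <- function(chs, reps, seed_tag)
      eval_channel_subset(subjects, chs, spec, cfg, layout_fn,
                          reps = reps, seed_tag = seed_tag)

  baseline <- eval_fn(channels, 1, "baseline")
  n_evals <- length(subjects)
  steps <- list()
  current <- channels
  termination <- "reached min_channels"

  repeat {
    n <- length(current)
    if (n <= protocol$min_channels) break
    if (n_evals >= protocol$max_evals) {
      termination <- "evaluation budget exhausted"
      break
    }

    if (n > 10) {
      # combinatorial phase: all subsets of size n-2
      subs <- utils::combn(current, n - 2L, simplify = FALSE)
      evals <- lapply(seq_along(subs), function(i)
        eval_fn(subs[[i]], 1, paste0("p1s", n, "c", i)))
      n_evals <- n_evals + length(subs) * length(subjects)
      acc <- vapply(evals, mean_acc, 0)
      ord <- order(acc, decreasing = TRUE)

      tally <- function(k_top, k_bot) {
        top <- unlist(subs[ord[seq_len(min(k_top, length(ord)))]])
        bot <- unlist(subs[ord[seq(length(ord), by = -1L,
                                   length.out = min(k_bot, length(ord)))]])
        vapply(current, function(ch) sum(bot == ch) - sum(top == ch), 0)
      }
      sc <- tally(protocol$top_k, protocol$bottom_k)
      worst2 <- function(sc) {
        o <- order(sc, decreasing = TRUE)
        list(chs = current[o[1:2]],
             tie = length(o) > 2 && sc[o[2]] == sc[o[3]])
      }
      pick <- worst2(sc)
      reason <- "frequency tally (top/bottom lists)"
      if (pick$tie) {
        sc2 <- tally(protocol$tie_expand, protocol$tie_expand)
        pick2 <- worst2(sc2)
        if (!pick2$tie) {
          pick <- pick2
          reason <- "frequency tally (expanded lists)"
        } else {
          # final fallback: keep the best-accuracy subset
          pick <- list(chs = setdiff(current, subs[[ord[1]]]))
          reason <- "best-subset accuracy fallback"
        }
      }
      removed <- pick$chs
      best_i <- ord[1]
      best_cvs <- evals[[best_i]]
      cand_tbl <- tibble::tibble(
        subset = vapply(subs, paste, "", collapse = ","),
        mean_acc = acc)
      new_current <- setdiff(current, removed)
      step_cvs <- eval_fn(new_current, 1, paste0("p1post", n))
      n_evals <- n_evals + length(subjects)
    } else {
      # leave-one-out phase
      subs <- lapply(seq_len(n), function(i) current[-i])
      evals <- lapply(seq_along(subs), function(i)
        eval_fn(subs[[i]], protocol$candidate_reps, paste0("p2s", n, "c", i)))
      n_evals <- n_evals + length(subs) * length(subjects) * protocol$candidate_reps
      acc <- vapply(evals, mean_acc, 0)
      best_i <- which.max(acc)
      new_current <- subs[[best_i]]
      removed <- setdiff(current, new_current)
      reason <- sprintf("best of %d leave-one-out subsets (mean acc %.4f)",
                        n, acc[best_i])
      step_cvs <- if (protocol$confirm_reps > protocol$candidate_reps) {
        n_evals <- n_evals + length(subjects) * protocol$confirm_reps
        eval_fn(new_current, protocol$confirm_reps, paste0("p2conf", n))
      } else evals[[best_i]]
      cand_tbl <- tibble::tibble(
        subset = vapply(subs, paste, "", collapse = ","),
        mean_acc = acc)
    }

    maintained <- all(mapply(accuracy_maintained, step_cvs, baseline))
    steps[[length(steps) + 1]] <- tibble::tibble(
      step = length(steps) + 1L,
      n_channels = length(new_current),
      removed = paste(removed, collapse = ","),
      reason = reason,
      mean_acc = mean_acc(step_cvs),
      maintained = maintained,
      candidates = list(cand_tbl),
      cv = list(step_cvs))

    if (!maintained) {
      termination <- "accuracy no longer maintained for all subjects"
      break
    }
    current <- new_current
  }

  structure(list(final_channels = current,
                 baseline = baseline,
                 steps = dplyr::bind_rows(steps),
                 termination = termination,
                 n_evaluations = n_evals),
            class = "channel_selection_trace")
}

#' @export
print.channel_selection_trace <- function(x, ...) {
  cat(sprintf("<channel_selection_trace> final set {%s} after %d steps (%s)\n",
              paste(x$final_channels, collapse = ", "), nrow(x$steps),
              x$termination))
  invisible(x)
}

sweep_one <- function(subjects, spec, cfg, layout_fn) {
  cvs <- lapply(seq_along(subjects), function(s) {
    std <- standardize(subjects[[s]]$train, list(subjects[[s]]$test))
    tr <- std$train; te <- std$others[[1]]
    if (inherits(spec, "proposed_3dcnn_spec")) {
      lay <- layout_fn(tr$channels)
      tr <- map_to_grid(tr, lay)
      te <- map_to_grid(te, lay)
    }
    cfg_s <- cfg
    cfg_s$shuffle_seed <- derive_seed(cfg$shuffle_seed, paste0("sweep-s", s))
    crossval_5fold(tr, te, spec, cfg_s)
  })
  cv_result(unlist(lapply(cvs, `[[`, "fold_acc")),
            do.call(c, lapply(cvs, `[[`, "confusions")))
}

#' Sample-window sweep
#'
#' Re-epochs the sessions at each candidate window length (all other
#' conditions fixed), runs the cross-validation protocol, and flags whether
#' each window maintains accuracy against the baseline.
#'
#' @param data One subject's `list(train =, test =)` of [raw_session()]s
#'   (or a list of such per subject).
#' @param spec Model specification.
#' @param windows Window lengths in seconds (reference grid: 4.0 down to
#'   0.5 in 0.5 s steps).
#' @param pp_spec Base [preprocess_spec()] (its `window_len_s` is swept).
#' @param cfg [train_config()] for each evaluation.
#' @param layout_fn Grid layout builder for the 3D-CNN.
#' @param baseline Optional [cv_result()]; defaults to the longest window's
#'   result.
#' @return A tibble of class `sweep_result`: one row per window with the
#'   accuracy summary, the maintenance flag, and the [cv_result()] as a
#'   list column.
#' @export
window_sweep <- function(data, spec, windows = seq(4, 0.5, by = -0.5),
                         pp_spec = preprocess_spec(), cfg = screening_config(),
                         layout_fn = layout_row, baseline = NULL) {
  subjects <- as_subject_list(data)
  filtered <- lapply(subjects, function(s)
    list(train = filter_session(s$train, pp_spec),
         test = filter_session(s$test, pp_spec)))
  rows <- lapply(windows, function(w) {
    pp <- pp_spec; pp$window_len_s <- w
    eps <- lapply(filtered, function(s)
      list(train = subsample(epoch(s$train, pp), pp$subsample_n),
           test = subsample(epoch(s$test, pp), pp$subsample_n)))
    cv <- sweep_one(eps, spec, cfg, layout_fn)
    tibble::tibble(window_len_s = w,
                   n_samples = dim(eps[[1]]$train$data)[3],
                   mean = cv$mean, min = cv$min, max = cv$max, std = cv$std,
                   kappa = cv$kappa, cv = list(cv))
  })
  out <- dplyr::bind_rows(rows)
  base <- baseline %||% out$cv[[which.max(out$window_len_s)]]
  out$maintained <- vapply(out$cv, accuracy_maintained, TRUE, baseline = base)
  structure(out, class = c("sweep_result", class(out)),
            sweep = "window", baseline = base)
}

#' Subsampling sweep
#'
#' Decimates the epoched data by each factor `n` (effective rate `fs/n`)
#' and evaluates the protocol per factor; otherwise as [window_sweep()].
#'
#' @param data,spec,pp_spec,cfg,layout_fn,baseline See [window_sweep()].
#' @param ns Subsampling factors (reference grid: 1 to 5).
#' @return A `sweep_result` tibble with one row per factor.
#' @export
subsample_sweep <- function(data, spec, ns = 1:5, pp_spec = preprocess_spec(),
                            cfg = screening_config(), layout_fn = layout_row,
                            baseline = NULL) {
  subjects <- as_subject_list(data)
  eps0 <- lapply(subjects, function(s)
    list(train = epoch(filter_session(s$train, pp_spec), pp_spec),
         test = epoch(filter_session(s$test, pp_spec), pp_spec)))
  rows <- lapply(ns, function(n) {
    eps <- lapply(eps0, function(s)
      list(train = subsample(s$train, n), test = subsample(s$test, n)))
    cv <- sweep_one(eps, spec, cfg, layout_fn)
    tibble::tibble(subsample_n = n,
                   fs_effective = eps[[1]]$train$fs_effective,
                   n_samples = dim(eps[[1]]$train$data)[3],
                   mean = cv$mean, min = cv$min, max = cv$max, std = cv$std,
                   kappa = cv$kappa, cv = list(cv))
  })
  out <- dplyr::bind_rows(rows)
  base <- baseline %||% out$cv[[which.min(out$subsample_n)]]
  out$maintained <- vapply(out$cv, accuracy_maintained, TRUE, baseline = base)
  structure(out, class = c("sweep_result", class(out)),
            sweep = "subsample", baseline = base)
}

#' Pareto front of model size versus accuracy
#'
#' Sorts configurations by parameter count (ascending; ties keep the higher
#' accuracy) and retains a point only when its accuracy strictly exceeds
#' every cheaper point's — the staircase of "accuracy records" as model
#' size grows.
#'
#' @param points Tibble/data.frame with columns `n_parameters` and
#'   `accuracy` (plus any identifier columns, carried through).
#' @return The front as a tibble of class `pareto_front` (all input points
#'   kept in attribute `"points"` for plotting).
#' @export
pareto_front <- function(points) {
  points <- tibble::as_tibble(points)
  assert_that(all(c("n_parameters", "accuracy") %in% names(points)),
              "points need columns n_parameters and accuracy")
  ord <- order(points$n_parameters, -points$accuracy)
  sorted <- points[ord, ]
  best <- -Inf
  keep <- logical(nrow(sorted))
  for (i in seq_len(nrow(sorted))) {
    if (sorted$accuracy[i] > best) {
      keep[i] <- TRUE
      best <- sorted$accuracy[i]
    }
  }
  structure(sorted[keep, ], class = c("pareto_front", class(points)),
            points = points)
}
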