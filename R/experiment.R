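# Experiment runner: one validated configuration drives every subcommand,
# a single global seed is expanded per component, and every artifact
# embeds the resolved configuration for provenance.

EXPERIMENT_COMMANDS <- c("simulate", "preprocess", "train", "crossval",
                         "select-channels", "sweep-window", "sweep-subsample",
                         "cost", "pareto", "erdmap", "describe")

#' Read an experiment configuration file
#'
#' @param path YAML or JSON file.
#' @return The configuration list (validated lazily by [run_experiment()]).
#' @export
read_experiment_config <- function(path) {
  assert_that(file.exists(path), paste0("no such config file: ", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

resolve_montage <- function(name) {
  switch(name %||% "montage_22",
         montage_22 = montage_22(), montage_8 = montage_8(),
         montage_iv2b = montage_iv2b(),
         stop("config error in field `dataset.montage`: unknown montage '",
              name, "'", call. = FALSE))
}

resolve_model_spec <- function(config) {
  m <- config$model %||% list(type = "proposed_3dcnn")
  type <- m$type %||% "proposed_3dcnn"
  args <- m[setdiff(names(m), "type")]
  switch(type,
         proposed_3dcnn = do.call(proposed_3dcnn_spec, args),
         eegnet = do.call(eegnet_spec, args),
         stop("config error in field `model.type`: unknown type '", type, "'",
              call. = FALSE))
}

resolve_layout <- function(config) {
  id <- config$grid %||% "row"
  if (identical(id, "row")) return(layout_row)
  if (!toupper(id) %in% c("A", "B", "C", "D", "E"))
    stop("config error in field `grid`: unknown layout id '", id, "'",
         call. = FALSE)
  function(channels) builtin_layout(id)
}

resolve_pp <- function(config) do.call(preprocess_spec, config$preprocess %||% list())

resolve_train_cfg <- function(config, seed) {
  args <- config$train %||% list()
  args$shuffle_seed <- derive_seed(seed, "train")
  do.call(train_config, args)
}

# materialize train/test raw sessions from the configured source
resolve_sessions <- function(config, seed) {
  ds <- config$dataset
  if (is.null(ds))
    stop("config error: field `dataset` is required", call. = FALSE)
  if (!is.null(ds$archive_train)) {
    list(train = load_archive(ds$archive_train),
         test = load_archive(ds$archive_test %||% ds$archive_train))
  } else if (!is.null(ds$archive)) {
    obj <- load_archive(ds$archive)
    list(train = obj, test = NULL)
  } else if (!is.null(ds$simulator)) {
    sim <- ds$simulator
    sim$montage <- resolve_montage(sim$montage)
    mk <- function(tag) {
      sim$seed <- derive_seed(seed, tag)
      simulate_session(do.call(sim_config, sim))$session
    }
    list(train = mk("sim-train"), test = mk("sim-test"))
  } else {
    stop("config error in field `dataset`: need `archive`, `archive_train`, ",
         "or `simulator`", call. = FALSE)
  }
}

as_epochs <- function(obj, pp) {
  if (inherits(obj, "epoched_dataset")) obj
  else preprocess_session(obj, pp)
}

prepare_model_data <- function(config, seed) {
  pp <- resolve_pp(config)
  ses <- resolve_sessions(config, seed)
  if (is.null(ses$test))
    stop("config error: this command needs train and test data ",
         "(`dataset.archive_train`/`archive_test` or `dataset.simulator`)",
         call. = FALSE)
  tr <- as_epochs(ses$train, pp)
  te <- as_epochs(ses$test, pp)
  std <- standardize(tr, list(te))
  list(train = std$train, test = std$others[[1]], pp = pp)
}

to_model_input <- function(ep, spec, layout_fn) {
  if (inherits(spec, "proposed_3dcnn_spec")) map_to_grid(ep, layout_fn(ep$channels))
  else ep
}

write_results <- function(out_dir, results, summary_tbl = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  if (!is.null(summary_tbl))
    utils::write.csv(summary_tbl, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  invisible(file.path(out_dir, "results.json"))
}

cv_summary_list <- function(cv) {
  list(fold_accuracies = cv$fold_acc, mean = cv$mean, min = cv$min,
       max = cv$max, std = cv$std, kappa = cv$kappa)
}

#' Run an experiment subcommand
#'
#' Single entry point behind the command-line front-end. Each command
#' validates its configuration, derives every component seed from the one
#' global `seed`, runs the corresponding pipeline, and writes
#' `results.json` (plus `summary.csv` where tabular) into `out_dir`. The
#' resolved configuration and seed are embedded in every `results.json`.
#'
#' @param config Configuration list (see the vignette) or a path readable
#'   by [read_experiment_config()]. Recognised fields include `seed`,
#'   `out_dir`, `dataset` (`archive`, `archive_train`/`archive_test`, or
#'   `simulator`), `preprocess`, `grid`, `model`, `train`, `protocol`,
#'   `windows`, `subsamples`, `erd`, `points`.
#' @param command One of `r paste(EXPERIMENT_COMMANDS, collapse = ", ")`.
#' @return Path of the written `results.json`, invisibly.
#' @export
run_experiment <- function(config, command) {
  if (is.character(config) && length(config) == 1) config <- read_experiment_config(config)
  if (!command %in% EXPERIMENT_COMMANDS)
    stop("config error in field `command`: unknown command '", command, "'",
         call. = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% stop("config error: field `out_dir` is required",
                                      call. = FALSE)
  provenance <- list(command = command, seed = seed,
                     config = config[setdiff(names(config), "out_dir")])
  res <- switch(command,
    simulate = {
      sim <- config$dataset$simulator %||%
        stop("config error: `dataset.simulator` is required for simulate",
             call. = FALSE)
      sim$montage <- resolve_montage(sim$montage)
      sim$seed <- derive_seed(seed, "sim-train")
      out <- simulate_session(do.call(sim_config, sim))
      write_archive(out$session, file.path(out_dir, "archive"),
                    provenance = provenance, overwrite = TRUE)
      list(archive = file.path(out_dir, "archive"),
           n_trials = nrow(out$truth),
           n_channels = nrow(out$session$signal),
           n_samples = ncol(out$session$signal), fs = out$session$fs)
    },
    preprocess = {
      pp <- resolve_pp(config)
      ses <- resolve_sessions(config, seed)
      ep <- as_epochs(ses$train, pp)
      write_archive(ep, file.path(out_dir, "epochs"),
                    provenance = provenance, overwrite = TRUE)
      list(archive = file.path(out_dir, "epochs"),
           n_trials = dim(ep$data)[1], n_channels = dim(ep$data)[2],
           n_samples = dim(ep$data)[3], fs_effective = ep$fs_effective)
    },
    train = {
      spec <- resolve_model_spec(config)
      layout_fn <- resolve_layout(config)
      dat <- prepare_model_data(config, seed)
      cfg <- resolve_train_cfg(config, seed)
      fold <- stratified_folds(dat$train$labels, 5L, derive_seed(seed, "split"))
      tr <- to_model_input(epochs_subset(dat$train, which(fold != 1L)), spec, layout_fn)
      va <- to_model_input(epochs_subset(dat$train, which(fold == 1L)), spec, layout_fn)
      fit <- train_model(tr, va, spec, cfg)
      te <- to_model_input(dat$test, spec, layout_fn)
      acc <- mean(predict(fit$model, te) == dat$test$labels)
      list(test_accuracy = acc, best_epoch = fit$best_epoch,
           epochs_run = nrow(fit$history),
           n_parameters = count_parameters(fit$model))
    },
    crossval = {
      spec <- resolve_model_spec(config)
      layout_fn <- resolve_layout(config)
      dat <- prepare_model_data(config, seed)
      cfg <- resolve_train_cfg(config, seed)
      cv <- crossval_5fold(to_model_input(dat$train, spec, layout_fn),
                           to_model_input(dat$test, spec, layout_fn),
                           spec, cfg)
      cv_summary_list(cv)
    },
    `select-channels` = {
      spec <- resolve_model_spec(config)
      layout_fn <- resolve_layout(config)
      dat <- prepare_model_data(config, seed)
      cfg <- resolve_train_cfg(config, seed)
      proto <- do.call(selection_protocol, config$protocol %||% list())
      trace <- channel_elimination_search(list(train = dat$train, test = dat$test),
                                          spec, proto, cfg, layout_fn)
      list(final_channels = trace$final_channels,
           n_steps = nrow(trace$steps),
           n_evaluations = trace$n_evaluations,
           termination = trace$termination,
           steps = tidy(trace))
    },
    `sweep-window` = {
      spec <- resolve_model_spec(config)
      ses <- resolve_sessions(config, seed)
      cfg <- resolve_train_cfg(config, seed)
      sw <- window_sweep(list(train = ses$train, test = ses$test), spec,
                         windows = config$windows %||% seq(4, 0.5, by = -0.5),
                         pp_spec = resolve_pp(config), cfg = cfg,
                         layout_fn = resolve_layout(config))
      list(table = dplyr::select(tibble::as_tibble(sw), -"cv"))
    },
    `sweep-subsample` = {
      spec <- resolve_model_spec(config)
      ses <- resolve_sessions(config, seed)
      cfg <- resolve_train_cfg(config, seed)
      sw <- subsample_sweep(list(train = ses$train, test = ses$test), spec,
                            ns = config$subsamples %||% 1:5,
                            pp_spec = resolve_pp(config), cfg = cfg,
                            layout_fn = resolve_layout(config))
      list(table = dplyr::select(tibble::as_tibble(sw), -"cv"))
    },
    cost = {
      spec <- resolve_model_spec(config)
      shp <- config$input_shape %||%
        stop("config error: field `input_shape` is required for cost ",
             "(list with T and n_channels or c1/c2)", call. = FALSE)
      model <- if (inherits(spec, "proposed_3dcnn_spec"))
        build_proposed_3dcnn(spec, shp$c1, shp$c2, shp$T)
      else build_eegnet(spec, shp$n_channels, shp$T)
      rep <- cost_report(model)
      list(n_parameters = attr(rep, "n_parameters"),
           parameters_k = attr(rep, "n_parameters") / 1e3,
           n_maccs = attr(rep, "n_maccs"),
           maccs_M = attr(rep, "n_maccs") / 1e6,
           memory_bytes = attr(rep, "memory_bytes"),
           memory_convention = "params+peak_act+input, batch1, float32")
    },
    describe = {
      spec <- resolve_model_spec(config)
      shp <- config$input_shape %||%
        stop("config error: field `input_shape` is required for describe",
             call. = FALSE)
      model <- if (inherits(spec, "proposed_3dcnn_spec"))
        build_proposed_3dcnn(spec, shp$c1, shp$c2, shp$T)
      else build_eegnet(spec, shp$n_channels, shp$T)
      list(layers = describe_model(model),
           n_parameters = count_parameters(model),
           n_maccs = count_maccs(model))
    },
    pareto = {
      pts <- tibble::as_tibble(config$points %||%
        stop("config error: field `points` is required for pareto",
             call. = FALSE))
      pf <- pareto_front(pts)
      list(front = tibble::as_tibble(pf))
    },
    erdmap = {
      ses <- resolve_sessions(config, seed)
      e <- config$erd %||% list()
      maps <- lapply(sort(unique(ses$train$events$code)), function(cl) {
        m <- erd_percent(ses$train, band = unlist(e$band %||% c(8, 12)),
                         baseline = unlist(e$baseline %||% c(0, 2)),
                         analysis = unlist(e$analysis %||% c(3.25, 7.25)),
                         classes = cl)
        tibble::tibble(class_code = cl, channel = m$channel, erd_pct = m$erd_pct)
      })
      list(erd = dplyr::bind_rows(maps))
    }
  )
  res$provenance <- provenance
  tab <- NULL
  for (f in c("table", "steps", "front", "erd", "layers"))
    if (!is.null(res[[f]])) tab <- res[[f]]
  path <- write_results(out_dir, res, tab)
  writeLines(c(paste("command:", command), paste("seed:", seed),
               paste("package: mieeg3d", as.character(utils::packageVersion("mieeg3d"))),
               paste("fields:", paste(names(res), collapse = ", "))),
             file.path(out_dir, "log.txt"))
  path
}
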