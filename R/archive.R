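# Trial archives: a directory holding compressed numeric arrays plus a JSON
# metadata sidecar. Round trips are bit-exact for arrays and lossless for
# metadata (schema version 1).

ARCHIVE_SCHEMA_VERSION <- 1L

#' Write a session or epoched dataset to a trial archive
#'
#' The archive is a directory containing `metadata.json` (schema, montage,
#' sampling, provenance) and `arrays.rds` (compressed numeric arrays).
#'
#' @param x A [raw_session()] or [epoched_dataset()].
#' @param path Directory to create (must not already contain an archive
#'   unless `overwrite = TRUE`).
#' @param provenance Optional named list stored verbatim in the sidecar
#'   (e.g. simulator config and seed).
#' @param overwrite Overwrite an existing archive at `path`.
#' @return `path`, invisibly.
#' @export
write_archive <- function(x, path, provenance = NULL, overwrite = FALSE) {
  assert_that(inherits(x, c("raw_session", "epoched_dataset")),
              "x must be a raw_session or epoched_dataset")
  if (dir.exists(path) && file.exists(file.path(path, "metadata.json")) && !overwrite)
    stop("archive already exists at ", path, call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)

  if (inherits(x, "raw_session")) {
    meta <- list(
      schema_version = ARCHIVE_SCHEMA_VERSION,
      kind = "raw_session",
      fs = x$fs,
      n_channels = nrow(x$signal),
      n_samples = ncol(x$signal),
      n_events = nrow(x$events),
      channels = x$montage$channel,
      grid_rows = x$montage$row,
      grid_cols = x$montage$col,
      subject_id = x$subject_id,
      session_id = x$session_id,
      event_codes = x$event_codes,
      provenance = provenance
    )
    arrays <- list(signal = x$signal,
                   event_sample = as.integer(x$events$sample),
                   event_code = as.integer(x$events$code))
  } else {
    meta <- list(
      schema_version = ARCHIVE_SCHEMA_VERSION,
      kind = "epoched_dataset",
      fs_effective = x$fs_effective,
      n_trials = dim(x$data)[1],
      n_channels = dim(x$data)[2],
      n_samples = dim(x$data)[3],
      n_classes = x$n_classes,
      channels = x$channels,
      grid_rows = if (!is.null(x$montage)) x$montage$row,
      grid_cols = if (!is.null(x$montage)) x$montage$col,
      window_start_s = x$window_start_s,
      window_len_s = x$window_len_s,
      subsample_n = x$subsample_n,
      provenance = provenance
    )
    arrays <- list(data = x$data, labels = x$labels)
  }
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  saveRDS(arrays, file.path(path, "arrays.rds"), compress = "gzip")
  invisible(path)
}

#' Load a trial archive
#'
#' @param path Archive directory written by [write_archive()].
#' @return A [raw_session()] or [epoched_dataset()], per the sidecar `kind`.
#'   Provenance metadata is attached as attribute `"provenance"`.
#' @export
load_archive <- function(path) {
  side <- file.path(path, "metadata.json")
  if (!file.exists(side))
    stop("format error: no metadata.json sidecar at ", path, call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$schema_version) || meta$schema_version > ARCHIVE_SCHEMA_VERSION)
    stop("format error: unrecognized archive schema version", call. = FALSE)
  arrays <- readRDS(file.path(path, "arrays.rds"))

  if (identical(meta$kind, "raw_session")) {
    if (!identical(dim(arrays$signal), c(meta$n_channels, meta$n_samples)) ||
        length(arrays$event_sample) != meta$n_events)
      stop("integrity error: array shapes disagree with the sidecar", call. = FALSE)
    coords <- stats::setNames(
      lapply(seq_along(meta$channels), function(i) c(meta$grid_rows[i], meta$grid_cols[i])),
      meta$channels)
    out <- raw_session(
      arrays$signal, fs = as.numeric(meta$fs),
      events = tibble::tibble(sample = arrays$event_sample, code = arrays$event_code),
      montage = montage_1010(meta$channels, coords),
      subject_id = meta$subject_id, session_id = meta$session_id,
      event_codes = meta$event_codes)
  } else if (identical(meta$kind, "epoched_dataset")) {
    if (!identical(dim(arrays$data),
                   c(meta$n_trials, meta$n_channels, meta$n_samples)))
      stop("integrity error: array shapes disagree with the sidecar", call. = FALSE)
    if (length(arrays$labels) != meta$n_trials)
      stop("integrity error: labels length differs from the number of trials",
           call. = FALSE)
    mont <- NULL
    if (!is.null(meta$grid_rows)) {
      coords <- stats::setNames(
        lapply(seq_along(meta$channels), function(i) c(meta$grid_rows[i], meta$grid_cols[i])),
        meta$channels)
      mont <- montage_1010(meta$channels, coords)
    }
    out <- epoched_dataset(
      arrays$data, labels = arrays$labels, channels = meta$channels,
      fs_effective = as.numeric(meta$fs_effective),
      window_start_s = as.numeric(meta$window_start_s),
      window_len_s = as.numeric(meta$window_len_s),
      subsample_n = meta$subsample_n,
      n_classes = meta$n_classes, montage = mont)
  } else {
    stop("format error: unknown archive kind ", meta$kind, call. = FALSE)
  }
  attr(out, "provenance") <- meta$provenance
  out
}
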