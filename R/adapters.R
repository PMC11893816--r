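# Read-only adapters for standard biosignal containers (EDF, GDF v2).
#
# Only the subset needed to ingest motor-imagery benchmark-style recordings
# is supported: uniformly sampled channels, one sampling rate, int16 EDF
# records, int16/float32/float64 GDF records, and (for GDF) the native event
# table. Classic EDF has no event table; events are recovered from a trigger
# channel (label TRIG, STATUS, EVENT or MARKER) as transitions to a nonzero
# value. Writing these formats is out of scope.

read_fixed_string <- function(con, n) {
  trimws(rawToChar(readBin(con, "raw", n)))
}

read_edf_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_fixed_string(con, 8L)
  invisible(readBin(con, "raw", 80L + 80L + 8L + 8L))    # patient, recording, date, time
  invisible(read_fixed_string(con, 8L))                  # header bytes
  invisible(readBin(con, "raw", 44L))                    # reserved
  n_records <- as.integer(read_fixed_string(con, 8L))
  record_dur <- as.numeric(read_fixed_string(con, 8L))
  ns <- as.integer(read_fixed_string(con, 4L))
  if (is.na(ns) || ns < 1) stop("unsupported format: malformed EDF header", call. = FALSE)

  labels   <- vapply(seq_len(ns), function(i) read_fixed_string(con, 16L), "")
  invisible(readBin(con, "raw", 80L * ns))               # transducer
  invisible(readBin(con, "raw", 8L * ns))                # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(read_fixed_string(con, 8L)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(read_fixed_string(con, 8L)), 0)
  dig_min  <- vapply(seq_len(ns), function(i) as.numeric(read_fixed_string(con, 8L)), 0)
  dig_max  <- vapply(seq_len(ns), function(i) as.numeric(read_fixed_string(con, 8L)), 0)
  invisible(readBin(con, "raw", 80L * ns))               # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(read_fixed_string(con, 8L)), 0L)
  invisible(readBin(con, "raw", 32L * ns))               # reserved

  if (length(unique(spr)) != 1)
    stop("unsupported format: EDF with per-channel sampling rates", call. = FALSE)
  fs <- spr[1] / record_dur

  sig <- matrix(0, nrow = ns, ncol = n_records * spr[1])
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      scale <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
      sig[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <-
        (dig - dig_min[i]) * scale + phys_min[i]
    }
  }
  list(version = version, labels = labels, fs = fs, signal = sig)
}

read_gdf_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- rawToChar(readBin(con, "raw", 8L))
  if (!startsWith(version, "GDF 2"))
    stop("unsupported format: only GDF v2 is supported (got '", trimws(version), "')",
         call. = FALSE)
  invisible(readBin(con, "raw", 216L))                   # patient/recording block
  n_records <- readBin(con, "integer", size = 8L, endian = "little")
  dur <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  ns <- readBin(con, "integer", size = 2L, signed = FALSE, endian = "little")
  invisible(readBin(con, "raw", 14L))                    # pad to 256

  labels <- vapply(seq_len(ns), function(i) read_fixed_string(con, 16L), "")
  invisible(readBin(con, "raw", 80L * ns))               # transducer
  invisible(readBin(con, "raw", 6L * ns))                # physical dimension (obsolete)
  invisible(readBin(con, "raw", 2L * ns))                # physical dimension code
  phys_min <- readBin(con, "double", n = ns, size = 8L, endian = "little")
  phys_max <- readBin(con, "double", n = ns, size = 8L, endian = "little")
  dig_min  <- readBin(con, "double", n = ns, size = 8L, endian = "little")
  dig_max  <- readBin(con, "double", n = ns, size = 8L, endian = "little")
  invisible(readBin(con, "raw", 68L * ns))               # prefilter string
  invisible(readBin(con, "raw", 12L * ns))               # lowpass/highpass/notch
  spr <- readBin(con, "integer", n = ns, size = 4L, endian = "little")
  gdftyp <- readBin(con, "integer", n = ns, size = 4L, endian = "little")
  invisible(readBin(con, "raw", 32L * ns))               # sensor pos/info/reserved

  if (length(unique(spr)) != 1)
    stop("unsupported format: GDF with per-channel sampling rates", call. = FALSE)
  fs <- spr[1] * dur[2] / dur[1]

  read_chan <- function(i) {
    switch(as.character(gdftyp[i]),
      "3"  = readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE, endian = "little"),
      "16" = readBin(con, "double", n = spr[i], size = 4L, endian = "little"),
      "17" = readBin(con, "double", n = spr[i], size = 8L, endian = "little"),
      stop("unsupported format: GDF channel type ", gdftyp[i], call. = FALSE))
  }
  sig <- matrix(0, nrow = ns, ncol = n_records * spr[1])
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      dig <- read_chan(i)
      denom <- dig_max[i] - dig_min[i]
      vals <- if (is.finite(denom) && denom != 0)
        (dig - dig_min[i]) * (phys_max[i] - phys_min[i]) / denom + phys_min[i]
      else dig
      sig[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <- vals
    }
  }

  events <- tibble::tibble(sample = integer(), code = integer())
  mode_raw <- readBin(con, "raw", 1L)
  if (length(mode_raw) == 1L) {
    mode <- as.integer(mode_raw)
    nev_b <- as.integer(readBin(con, "raw", 3L))
    nev <- nev_b[1] + 256L * nev_b[2] + 65536L * nev_b[3]
    invisible(readBin(con, "raw", 4L))                   # event sample rate
    if (nev > 0) {
      pos <- readBin(con, "integer", n = nev, size = 4L, endian = "little")
      typ <- readBin(con, "integer", n = nev, size = 2L, signed = FALSE, endian = "little")
      events <- tibble::tibble(sample = as.integer(pos - 1L), code = as.integer(typ))
    }
    if (!mode %in% c(1L, 3L) && nev > 0)
      warning("GDF event table mode ", mode, "; positions/types read as mode 1")
  }
  list(version = version, labels = labels, fs = fs, signal = sig, events = events)
}

trigger_events <- function(labels, signal) {
  trig_i <- which(toupper(labels) %in% c("TRIG", "STATUS", "EVENT", "MARKER"))
  if (length(trig_i) == 0) return(tibble::tibble(sample = integer(), code = integer()))
  tr <- round(signal[trig_i[1], ])
  changed <- which(tr != 0 & c(0, tr[-length(tr)]) != tr)
  tibble::tibble(sample = as.integer(changed - 1L), code = as.integer(tr[changed]))
}

#' Import an external EDF/GDF recording as a session
#'
#' Reads a standard biosignal file, extracts events, and reorders the
#' channels to the requested montage order. For classic EDF (which has no
#' event table) events are taken from a trigger channel labelled TRIG,
#' STATUS, EVENT or MARKER: each transition to a nonzero value becomes one
#' event with the channel value as its code. GDF v2 files use the native
#' event table (positions converted to 0-based samples). Dataset-native
#' event codes are not translated; pass `event_code_map` to relabel them.
#'
#' @param path File path.
#' @param format `"edf"` or `"gdf"`.
#' @param montage Target [montage_1010()]; all its channels must be present
#'   in the file header (case-insensitive).
#' @param event_code_map Optional named translation, e.g. `c("769" = 0)`:
#'   events with codes absent from the map are dropped.
#' @param subject_id,session_id Identifiers for the resulting session.
#' @return A [raw_session()] with channels in montage order.
#' @export
adapt_external <- function(path, format = c("edf", "gdf"), montage,
                           event_code_map = NULL,
                           subject_id = "S01", session_id = "T") {
  format <- match.arg(format)
  assert_that(file.exists(path), paste0("no such file: ", path))
  parsed <- switch(format, edf = read_edf_file(path), gdf = read_gdf_file(path))

  idx <- match(toupper(montage$channel), toupper(parsed$labels))
  if (anyNA(idx))
    stop("channel(s) absent from ", toupper(format), " header: ",
         paste(montage$channel[is.na(idx)], collapse = ", "), call. = FALSE)
  signal <- parsed$signal[idx, , drop = FALSE]

  events <- parsed$events %||% trigger_events(parsed$labels, parsed$signal)
  if (!is.null(event_code_map)) {
    keep <- as.character(events$code) %in% names(event_code_map)
    events <- events[keep, ]
    events$code <- as.integer(event_code_map[as.character(events$code)])
  }
  raw_session(signal, fs = parsed$fs, events = events, montage = montage,
              subject_id = subject_id, session_id = session_id,
              event_codes = as.list(event_code_map))
}
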