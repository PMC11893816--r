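# Electrode montages on a reference 6 x 7 scalp grid.
#
# The grid covers the motor/parietal field of the 10-10 system used by the
# 22-channel wet-electrode layout: row 0 is the frontal (nasion) side,
# column 0 the left hemisphere, column 3 the midline.

# channel -> (row, col) on the reference 6 x 7 grid (0-based)
.GRID_COORDS_22 <- list(
  FZ  = c(0L, 3L),
  FC3 = c(1L, 1L), FC1 = c(1L, 2L), FCZ = c(1L, 3L), FC2 = c(1L, 4L), FC4 = c(1L, 5L),
  C5  = c(2L, 0L), C3  = c(2L, 1L), C1  = c(2L, 2L), CZ  = c(2L, 3L),
  C2  = c(2L, 4L), C4  = c(2L, 5L), C6  = c(2L, 6L),
  CP3 = c(3L, 1L), CP1 = c(3L, 2L), CPZ = c(3L, 3L), CP2 = c(3L, 4L), CP4 = c(3L, 5L),
  P1  = c(4L, 2L), PZ  = c(4L, 3L), P2  = c(4L, 4L),
  POZ = c(5L, 3L)
)

.CHANNELS_22 <- names(.GRID_COORDS_22)
.CHANNELS_8 <- c("C5", "C3", "CZ", "C4", "CP1", "CP2", "CP4", "POZ")
.CHANNELS_IV2B <- c("C3", "CZ", "C4")

#' Construct an electrode montage
#'
#' A montage is an ordered set of 10-10 channel labels together with each
#' channel's cell on the reference 6 x 7 scalp grid (row 0 frontal, column 0
#' left hemisphere). Channel names must be unique and no two channels may
#' share a grid cell.
#'
#' @param channels Character vector of channel labels.
#' @param coords Optional list mapping each label to a `c(row, col)` pair
#'   (0-based). Defaults to the built-in 10-10 coordinates.
#' @return A tibble of class `montage` with columns `channel`, `row`, `col`.
#' @examples
#' montage_1010(c("C3", "CZ", "C4"))
#' @export
montage_1010 <- function(channels, coords = NULL) {
  channels <- toupper(as.character(channels))
  assert_that(length(channels) >= 1, "montage needs at least one channel")
  assert_that(!anyDuplicated(channels), "montage channel names must be unique")
  coords <- coords %||% .GRID_COORDS_22
  missing <- setdiff(channels, names(coords))
  assert_that(
    length(missing) == 0,
    paste0("no grid coordinates for channel(s): ", paste(missing, collapse = ", "))
  )
  rc <- do.call(rbind, coords[channels])
  out <- tibble::tibble(channel = channels, row = as.integer(rc[, 1]), col = as.integer(rc[, 2]))
  key <- paste(out$row, out$col)
  assert_that(!anyDuplicated(key), "two montage channels share a grid cell")
  class(out) <- c("montage", class(out))
  out
}

#' Built-in montages
#'
#' `montage_22()` is the 22-channel wet-electrode layout; `montage_8()` the
#' eight motor-cortex channels C5, C3, CZ, C4, CP1, CP2, CP4, POZ retained by
#' the staged channel-elimination search; `montage_iv2b()` the bipolar-like
#' 3-channel layout C3, CZ, C4.
#'
#' @return A [montage_1010()] object.
#' @export
montage_22 <- function() montage_1010(.CHANNELS_22)

#' @rdname montage_22
#' @export
montage_8 <- function() montage_1010(.CHANNELS_8)

#' @rdname montage_22
#' @export
montage_iv2b <- function() montage_1010(.CHANNELS_IV2B)

#' Restrict a montage to a subset of channels
#'
#' @param montage A [montage_1010()] object.
#' @param channels Channel labels to keep (order taken from `channels`).
#' @return A `montage` with only the requested channels.
#' @export
montage_subset <- function(montage, channels) {
  channels <- toupper(channels)
  missing <- setdiff(channels, montage$channel)
  assert_that(
    length(missing) == 0,
    paste0("channel(s) not in montage: ", paste(missing, collapse = ", "))
  )
  out <- montage[match(channels, montage$channel), ]
  class(out) <- c("montage", setdiff(class(out), "montage"))
  out
}

is_montage <- function(x) inherits(x, "montage")

# hemisphere of each montage channel relative to the midline column (3):
# -1 left, 0 midline, +1 right
montage_side <- function(montage) {
  sign(montage$col - 3L)
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", nrow(x), " channels: ", paste(x$channel, collapse = ", "), "\n", sep = "")
  invisible(x)
}
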