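# Mapping channel-ordered epochs onto scalp-grid tensors. Five built-in
# layouts: A (6x7, 8 channels at true scalp positions), B (3x3), C (2x4),
# D (1x8) compressed rearrangements of the 8-channel set, and E (6x7, all
# 22 channels). Grid cells without an electrode are zero-filled.

#' Construct a grid layout
#'
#' @param layout_id Identifier string (e.g. `"A"` or `"custom"`).
#' @param c1,c2 Grid rows and columns.
#' @param cell_map Tibble/data.frame with columns `channel`, `row`, `col`
#'   (0-based grid coordinates); cells must be distinct and inside the grid.
#' @return An object of class `grid_layout`.
#' @export
grid_layout <- function(layout_id, c1, c2, cell_map) {
  cell_map <- tibble::as_tibble(cell_map)
  assert_that(all(c("channel", "row", "col") %in% names(cell_map)),
              "cell_map needs columns channel, row, col")
  assert_that(all(cell_map$row >= 0 & cell_map$row < c1 &
                    cell_map$col >= 0 & cell_map$col < c2),
              "cell_map coordinates must lie inside the grid")
  key <- paste(cell_map$row, cell_map$col)
  assert_that(!anyDuplicated(key), "cell_map cells must be distinct")
  assert_that(!anyDuplicated(cell_map$channel), "cell_map channels must be unique")
  structure(list(layout_id = layout_id, c1 = as.integer(c1), c2 = as.integer(c2),
                 cell_map = cell_map),
            class = "grid_layout")
}

# reading-order packing of the 8-channel set used by layouts B, C, D
.PACK_ORDER_8 <- c("C5", "C3", "CZ", "C4", "CP1", "CP2", "CP4", "POZ")

pack_row_major <- function(channels, c1, c2) {
  idx <- seq_along(channels) - 1L
  tibble::tibble(channel = channels,
                 row = as.integer(idx %/% c2),
                 col = as.integer(idx %% c2))
}

#' Built-in grid layouts
#'
#' `"A"` places the 8 retained channels at their true positions on the
#' 6 x 7 scalp grid; `"B"` (3 x 3), `"C"` (2 x 4) and `"D"` (1 x 8) pack the
#' same 8 channels row-major in scalp reading order (C5, C3, CZ, C4 / CP1,
#' CP2, CP4 / POZ); `"E"` places all 22 channels at their scalp positions.
#' The packed assignments for B-D are a convention, not a constraint:
#' classification accuracy is insensitive to the rearrangement, and custom
#' maps can be supplied through [grid_layout()].
#'
#' @param layout_id One of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`.
#' @return A [grid_layout()].
#' @export
builtin_layout <- function(layout_id) {
  m22 <- montage_22()
  switch(toupper(layout_id),
    A = grid_layout("A", 6, 7, montage_subset(m22, .PACK_ORDER_8)[, c("channel", "row", "col")]),
    B = grid_layout("B", 3, 3, pack_row_major(.PACK_ORDER_8, 3, 3)),
    C = grid_layout("C", 2, 4, pack_row_major(.PACK_ORDER_8, 2, 4)),
    D = grid_layout("D", 1, 8, pack_row_major(.PACK_ORDER_8, 1, 8)),
    E = grid_layout("E", 6, 7, m22[, c("channel", "row", "col")]),
    stop("unknown layout id: ", layout_id, call. = FALSE))
}

#' Single-row layout for an arbitrary channel set
#'
#' Convenience builder used when sweeping channel subsets: a degenerate
#' 1 x n grid in the given channel order.
#'
#' @param channels Character channel labels.
#' @return A [grid_layout()].
#' @export
layout_row <- function(channels) {
  grid_layout(paste0("row", length(channels)), 1, length(channels),
              pack_row_major(channels, 1, length(channels)))
}

#' Map epochs onto grid tensors
#'
#' Each trial becomes a `(1, C1, C2, T)` tensor: the value at a channel's
#' cell is that channel's time series and every unmapped cell is exactly
#' zero, so summing over grid cells recovers the channel sum (the embedding
#' is lossless).
#'
#' @param ep An [epoched_dataset()]; every channel must appear in the
#'   layout's cell map (extra mapped cells are allowed and stay zero).
#' @param layout A [grid_layout()].
#' @return An object of class `grid_dataset`: list with `values` (array
#'   trials x C1 x C2 x T), `layout`, `labels`, `n_classes`, `fs_effective`.
#' @export
map_to_grid <- function(ep, layout) {
  stopifnot(inherits(ep, "epoched_dataset"), inherits(layout, "grid_layout"))
  pos <- match(toupper(ep$channels), toupper(layout$cell_map$channel))
  if (anyNA(pos))
    stop("channel(s) not in grid layout: ",
         paste(ep$channels[is.na(pos)], collapse = ", "), call. = FALSE)
  d <- dim(ep$data)
  vals <- array(0, c(d[1], layout$c1, layout$c2, d[3]))
  for (j in seq_along(pos)) {
    r <- layout$cell_map$row[pos[j]] + 1L
    c <- layout$cell_map$col[pos[j]] + 1L
    vals[, r, c, ] <- ep$data[, j, ]
  }
  structure(list(values = vals, layout = layout, labels = ep$labels,
                 n_classes = ep$n_classes, fs_effective = ep$fs_effective),
            class = "grid_dataset")
}

#' @export
print.grid_layout <- function(x, ...) {
  cat(sprintf("<grid_layout %s> %d x %d, %d mapped cells\n",
              x$layout_id, x$c1, x$c2, nrow(x$cell_map)))
  invisible(x)
}

#' @export
print.grid_dataset <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<grid_dataset> %d trials on %d x %d grid, T = %d\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}
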