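#' Tile layout of a composite image
#'
#' Motorized-stage acquisitions store each field as a composite of tiles on
#' a known grid (2 x 3 for the single-cell infection analysis, 2 x 2 for
#' the autophagy quantification). Tiles are processed independently and
#' their ROI tables concatenated with tile offsets; no cross-tile object
#' merging is attempted, so cells split across a seam are counted per tile.
#'
#' @param rows,cols Tile grid dimensions (>= 1).
#' @return A list of class `composite_layout`.
#' @export
composite_layout <- function(rows, cols) {
  if (rows < 1 || cols < 1) {
    stop("`rows` and `cols` must be >= 1", call. = FALSE)
  }
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols)),
    class = "composite_layout"
  )
}

#' Split a composite image into tiles
#'
#' Cuts the image into an exact `rows x cols` grid in row-major order,
#' recording each tile's 0-based pixel offset so ROI coordinates measured
#' per tile can be mapped back into the composite frame.
#'
#' @param img Numeric matrix or `image_plane`; its dimensions must be
#'   divisible by the grid.
#' @param layout A [composite_layout()] (or `c(rows, cols)`).
#' @return A tibble with one row per tile: `tile_id`, `tile_row`,
#'   `tile_col`, `row_offset`, `col_offset` (0-based px) and `tile` (a
#'   list-column of matrices).
#' @export
#'
#' @examples
#' tiles <- split_composite(matrix(1:100, 10, 10), composite_layout(2, 2))
#' tiles$row_offset
split_composite <- function(img, layout) {
  if (is.numeric(layout) && length(layout) == 2L) {
    layout <- composite_layout(layout[1], layout[2])
  }
  stopifnot(inherits(layout, "composite_layout"))
  check_image(img)
  h <- nrow(img)
  w <- ncol(img)
  if (h %% layout$rows != 0L || w %% layout$cols != 0L) {
    stop(sprintf(
      "image %d x %d is not divisible by the %d x %d grid (remainders %d, %d)",
      h, w, layout$rows, layout$cols, h %% layout$rows, w %% layout$cols
    ), call. = FALSE)
  }
  th <- h %/% layout$rows
  tw <- w %/% layout$cols
  grid <- expand.grid(tile_col = seq_len(layout$cols), tile_row = seq_len(layout$rows))
  grid <- grid[order(grid$tile_row, grid$tile_col), ]
  m <- as_pixel_matrix(img)
  tibble::tibble(
    tile_id = seq_len(nrow(grid)),
    tile_row = grid$tile_row,
    tile_col = grid$tile_col,
    row_offset = (grid$tile_row - 1L) * th,
    col_offset = (grid$tile_col - 1L) * tw,
    tile = purrr::map2(grid$tile_row, grid$tile_col, function(i, j) {
      m[(i - 1L) * th + seq_len(th), (j - 1L) * tw + seq_len(tw), drop = FALSE]
    })
  )
}

#' Reassemble tiles into the composite image
#'
#' Inverse of [split_composite()]: placing every tile at its recorded
#' offset reproduces the composite exactly.
#'
#' @param tiles Tibble from [split_composite()].
#' @return A numeric matrix.
#' @export
assemble_composite <- function(tiles) {
  th <- nrow(tiles$tile[[1]])
  tw <- ncol(tiles$tile[[1]])
  h <- max(tiles$row_offset) + th
  w <- max(tiles$col_offset) + tw
  out <- matrix(0, h, w)
  for (k in seq_len(nrow(tiles))) {
    out[
      tiles$row_offset[k] + seq_len(th),
      tiles$col_offset[k] + seq_len(tw)
    ] <- tiles$tile[[k]]
  }
  out
}
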