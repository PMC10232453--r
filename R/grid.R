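#' Define a regular raster grid
#'
#' A `grid_spec` describes a regular, axis-aligned raster: its dimensions,
#' the map coordinates of the outer corner of the upper-left cell, the cell
#' size, and a coordinate reference system identifier. Row 1 is the
#' northernmost row, so for a north-up geographic grid `pixel_size_y` is
#' negative. Cell centers sit at `origin + (index - 0.5) * pixel_size`
#' (1-based indices).
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param origin_x,origin_y Map coordinates of the outer corner of the
#'   upper-left cell (its north-west corner).
#' @param pixel_size_x,pixel_size_y Cell size in map units per pixel.
#'   `pixel_size_y` is typically negative (rows run north to south).
#' @param crs_id Text identifier of the coordinate reference system.
#'   Defaults to `"GCS_WGS_1984"` (geographic WGS-84, EPSG:4326).
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(3616, 10000, origin_x = -180, origin_y = 70,
#'                pixel_size_x = 0.036, pixel_size_y = -0.036)
#' @export
grid_spec <- function(n_rows, n_cols,
                      origin_x = 0, origin_y = n_rows,
                      pixel_size_x = 1, pixel_size_y = -1,
                      crs_id = "GCS_WGS_1984") {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("grid dimensions must be >= 1")
  if (!is.finite(origin_x) || !is.finite(origin_y))
    stop("grid origin must be finite")
  if (!is.finite(pixel_size_x) || pixel_size_x == 0 ||
      !is.finite(pixel_size_y) || pixel_size_y == 0)
    stop("pixel sizes must be finite and nonzero")
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         pixel_size_x = as.numeric(pixel_size_x),
         pixel_size_y = as.numeric(pixel_size_y),
         crs_id = as.character(crs_id)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d rows x %d cols, origin (%g, %g), pixel (%g, %g), crs %s\n",
              x$n_rows, x$n_cols, x$origin_x, x$origin_y,
              x$pixel_size_x, x$pixel_size_y, x$crs_id))
  invisible(x)
}

#' Compare two grids for equality
#'
#' Grids are equal when dimensions and CRS match exactly and all coordinates
#' (origin, pixel sizes) agree within an absolute tolerance.
#'
#' @param a,b `grid_spec` objects.
#' @param tol Absolute tolerance on coordinates, in map units.
#' @return Logical scalar.
#' @export
grid_equal <- function(a, b, tol = 1e-9) {
  stopifnot(inherits(a, "grid_spec"), inherits(b, "grid_spec"))
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    identical(a$crs_id, b$crs_id) &&
    abs(a$origin_x - b$origin_x) <= tol &&
    abs(a$origin_y - b$origin_y) <= tol &&
    abs(a$pixel_size_x - b$pixel_size_x) <= tol &&
    abs(a$pixel_size_y - b$pixel_size_y) <= tol
}

#' Cell-center coordinates of a grid
#'
#' @param grid A `grid_spec`.
#' @return A list with numeric vectors `x` (length `n_cols`) and `y`
#'   (length `n_rows`) of cell-center map coordinates.
#' @export
grid_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  list(
    x = grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$pixel_size_x,
    y = grid$origin_y + (seq_len(grid$n_rows) - 0.5) * grid$pixel_size_y
  )
}
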