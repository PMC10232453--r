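#' Gridded index time series (raster cube)
#'
#' A `raster_cube` holds a (time x row x col) stack of one gridded variable
#' (NDVI, LST, VCI, TCI, VHI, or a reference drought index), together with
#' its grid, its time labels, and an explicit validity mask. Missing data are
#' carried in the mask, never as a sentinel value; the -9999 background code
#' only appears at file boundaries (see [read_cube()] / [write_cube()]).
#'
#' @param values Numeric (or logical) array with dim `(n_times, n_rows,
#'   n_cols)`.
#' @param times Time labels: an integer vector of years, or a data frame
#'   with column `year` plus optionally `month` (1-12) or `week` (1-53).
#'   Must be strictly increasing.
#' @param grid A [grid_spec()] matching the spatial dimensions of `values`.
#' @param valid Logical array of the same dimension; defaults to
#'   `is.finite(values)`. Values at invalid cells are never used.
#' @return An object of class `raster_cube`.
#' @export
raster_cube <- function(values, times, grid, valid = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3-d array (time x row x col)")
  times <- as_time_table(times)
  d <- dim(values)
  if (d[1L] != nrow(times))
    stop("number of time steps in 'values' (", d[1L],
         ") does not match 'times' (", nrow(times), ")")
  if (d[2L] != grid$n_rows || d[3L] != grid$n_cols)
    stop("spatial dimensions of 'values' (", d[2L], " x ", d[3L],
         ") do not match the grid (", grid$n_rows, " x ", grid$n_cols, ")")
  if (is.null(valid)) {
    valid <- is.finite(values)
  } else {
    if (!is.logical(valid) || !identical(dim(valid), d))
      stop("'valid' must be a logical array with the same dimensions as 'values'")
    valid <- valid & is.finite(values)
  }
  k <- time_order_key(times)
  if (nrow(times) > 1L && any(diff(k) <= 0))
    stop("'times' must be strictly increasing")
  structure(
    list(values = values, valid = valid, times = times, grid = grid),
    class = "raster_cube"
  )
}

# Normalize time labels to a data frame with column year (+ month or week).
as_time_table <- function(times) {
  if (is.data.frame(times)) {
    if (!"year" %in% names(times)) stop("'times' needs a 'year' column")
    extra <- setdiff(names(times), c("year", "month", "week"))
    if (length(extra))
      stop("unknown time columns: ", paste(extra, collapse = ", "))
    if (all(c("month", "week") %in% names(times)))
      stop("'times' may carry 'month' or 'week', not both")
    out <- data.frame(year = as.integer(times$year))
    if ("month" %in% names(times)) {
      out$month <- as.integer(times$month)
      if (any(out$month < 1L | out$month > 12L)) stop("month out of 1..12")
    }
    if ("week" %in% names(times)) {
      out$week <- as.integer(times$week)
      if (any(out$week < 1L | out$week > 53L)) stop("week out of 1..53")
    }
    if (anyNA(out)) stop("time labels contain NA")
    return(out)
  }
  if (is.numeric(times)) {
    if (anyNA(times)) stop("time labels contain NA")
    return(data.frame(year = as.integer(times)))
  }
  stop("'times' must be a numeric vector of years or a data frame")
}

# Monotone integer key for ordering time labels.
time_order_key <- function(times) {
  k <- times$year * 1000L
  if ("month" %in% names(times)) k <- k + times$month
  if ("week" %in% names(times)) k <- k + times$week
  k
}

#' @rdname raster_cube
#' @param x,cube A `raster_cube`.
#' @export
time_resolution <- function(cube) {
  stopifnot(inherits(cube, "raster_cube"))
  if ("week" %in% names(cube$times)) return("weekly")
  if ("month" %in% names(cube$times)) return("monthly")
  "annual"
}

#' @export
print.raster_cube <- function(x, ...) {
  cat(sprintf("raster_cube: %d time steps (%s) on %d x %d grid; %.1f%% valid\n",
              nrow(x$times), time_resolution(x),
              x$grid$n_rows, x$grid$n_cols,
              100 * mean(x$valid)))
  invisible(x)
}

#' @export
dim.raster_cube <- function(x) dim(x$values)

# View the cube as (time x pixel) matrices; pixel index is r + (c-1)*n_rows,
# i.e. the natural column-major collapse of the (row, col) dimensions.
cube_matrices <- function(cube) {
  d <- dim(cube$values)
  v <- cube$values; dim(v) <- c(d[1L], d[2L] * d[3L])
  m <- cube$valid;  dim(m) <- c(d[1L], d[2L] * d[3L])
  list(values = v, valid = m)
}

# Rebuild a cube from (time x pixel) matrices on the same grid.
cube_from_matrices <- function(values, valid, times, grid) {
  dim(values) <- c(nrow(as_time_table(times)), grid$n_rows, grid$n_cols)
  dim(valid) <- dim(values)
  raster_cube(values, times, grid, valid)
}

# Stop unless two cubes share grid and time axis.
check_aligned <- function(a, b, what = c("grid", "times")) {
  if ("grid" %in% what && !grid_equal(a$grid, b$grid))
    stop("cubes are on different grids")
  if ("times" %in% what && !identical(a$times, b$times))
    stop("cubes have different time axes")
  invisible(TRUE)
}

#' Extract one pixel's time series
#'
#' @param cube A `raster_cube`.
#' @param row,col 1-based pixel indices.
#' @return Numeric vector of length `n_times` with `NA` at invalid steps.
#' @export
pixel_series <- function(cube, row, col) {
  stopifnot(inherits(cube, "raster_cube"))
  v <- cube$values[, row, col]
  v[!cube$valid[, row, col]] <- NA_real_
  as.numeric(v)
}
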