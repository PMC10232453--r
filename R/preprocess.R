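# Temporal aggregation and grid matching for index cubes.

# Month containing the start date of ISO-style week w of a year: day
# (w-1)*7 + 1. Weeks straddling a month boundary belong to the month in
# which they start.
week_to_month <- function(year, week) {
  as.POSIXlt(as.Date(sprintf("%d-01-01", year)) + (week - 1L) * 7L)$mon + 1L
}

#' Aggregate a cube to a coarser time resolution
#'
#' Computes per-cell arithmetic means of valid values over each target
#' period (weekly to monthly or annual, monthly to annual). A weekly step is
#' assigned to the month containing its start date. An output cell is valid
#' when at least `min_count` valid input steps fall in its period; by
#' default a single available observation is enough, matching the practice
#' of averaging whatever weeks are present.
#'
#' @param cube A [raster_cube()].
#' @param target `"annual"` or `"monthly"`.
#' @param min_count Minimum number of valid input steps per period.
#' @return A [raster_cube()] at the target resolution.
#' @export
aggregate_time <- function(cube, target = c("annual", "monthly"), min_count = 1L) {
  stopifnot(inherits(cube, "raster_cube"))
  target <- match.arg(target)
  res <- time_resolution(cube)
  if (res == "annual")
    stop("cube is already annual; cannot aggregate to ", target)
  if (target == "monthly" && res != "weekly")
    stop("monthly aggregation requires a weekly cube, got ", res)
  if (min_count < 1L) stop("'min_count' must be >= 1")

  if (target == "annual") {
    key <- cube$times$year
    out_times <- data.frame(year = sort(unique(key)))
    key_levels <- out_times$year
  } else {
    mon <- week_to_month(cube$times$year, cube$times$week)
    key <- cube$times$year * 100L + mon
    key_levels <- sort(unique(key))
    out_times <- data.frame(year = key_levels %/% 100L, month = key_levels %% 100L)
  }
  m <- cube_matrices(cube)
  v <- m$values; v[!m$valid] <- 0
  grp <- factor(key, levels = key_levels)
  sums <- rowsum(v, grp, reorder = FALSE)
  cnts <- rowsum(m$valid + 0, grp, reorder = FALSE)
  ok <- cnts >= min_count
  means <- ifelse(ok, sums / pmax(cnts, 1), NA_real_)
  cube_from_matrices(means, ok, out_times, cube$grid)
}

# Index of the source cell whose center is nearest to coordinate 'x' along
# one axis; exact ties go to the smaller index. NA when outside the source
# extent's nearest-cell range.
nearest_index <- function(x, origin, pixel_size, n) {
  u <- (x - origin) / pixel_size - 0.5       # 0-based real-valued position
  i <- ceiling(u - 0.5) + 1                  # ties -> smaller index
  i[i < 1 | i > n] <- NA_integer_
  as.integer(i)
}

#' Resample a cube onto another grid by nearest neighbor
#'
#' Each target cell takes the value and validity of the source cell whose
#' center is nearest to the target cell center; there is no interpolation,
#' matching how a coarse reference drought index is brought onto a finer
#' satellite grid. Target cells falling outside the source extent are
#' invalid. Exact center ties resolve to the smaller (row, col) index.
#'
#' @param source A [raster_cube()].
#' @param target_grid A [grid_spec()] sharing the source CRS.
#' @return A [raster_cube()] on `target_grid` with the source time axis.
#' @export
resample_nearest <- function(source, target_grid) {
  stopifnot(inherits(source, "raster_cube"), inherits(target_grid, "grid_spec"))
  sg <- source$grid
  if (!identical(sg$crs_id, target_grid$crs_id))
    stop("CRS mismatch ('", sg$crs_id, "' vs '", target_grid$crs_id,
         "'); reprojection is not supported")
  ctr <- grid_centers(target_grid)
  ri <- nearest_index(ctr$y, sg$origin_y, sg$pixel_size_y, sg$n_rows)
  ci <- nearest_index(ctr$x, sg$origin_x, sg$pixel_size_x, sg$n_cols)
  rok <- !is.na(ri); cok <- !is.na(ci)
  ri[!rok] <- 1L; ci[!cok] <- 1L
  values <- source$values[, ri, ci, drop = FALSE]
  valid <- source$valid[, ri, ci, drop = FALSE]
  if (!all(rok)) valid[, !rok, ] <- FALSE
  if (!all(cok)) valid[, , !cok] <- FALSE
  values[!valid] <- NA_real_
  raster_cube(values, source$times, target_grid, valid)
}
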