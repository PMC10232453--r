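# VCI, TCI, weighted VHI, and the seven-class drought scale.

# Min-max scaling of a cube to [0, 100], per pixel across time (the
# operational multi-year climatology convention) or against the global
# extrema over all pixels and periods. 'invert = TRUE' gives the thermal
# convention: the historical maximum maps to 0.
scaled_extreme_index <- function(cube, invert, scope = c("pixel", "global")) {
  stopifnot(inherits(cube, "raster_cube"))
  scope <- match.arg(scope)
  if (all(!cube$valid)) stop("cube has no valid values")
  m <- cube_matrices(cube)
  v <- m$values; v[!m$valid] <- NA_real_
  if (scope == "pixel") {
    mn <- suppressWarnings(apply(v, 2L, min, na.rm = TRUE))
    mx <- suppressWarnings(apply(v, 2L, max, na.rm = TRUE))
  } else {
    mn <- rep(min(v, na.rm = TRUE), ncol(v))
    mx <- rep(max(v, na.rm = TRUE), ncol(v))
  }
  rng <- mx - mn
  usable <- is.finite(rng) & rng > 0          # >= 2 distinct valid values
  nt <- nrow(v)
  lo <- matrix(mn, nt, length(mn), byrow = TRUE)
  span <- matrix(rng, nt, length(rng), byrow = TRUE)
  out <- if (invert) (lo + span - v) / span * 100 else (v - lo) / span * 100
  ok <- m$valid & matrix(usable, nt, length(usable), byrow = TRUE)
  out[!ok] <- NA_real_
  cube_from_matrices(out, ok, cube$times, cube$grid)
}

#' Vegetation Condition Index from an NDVI cube
#'
#' `VCI = (NDVI - NDVI_MIN) / (NDVI_MAX - NDVI_MIN) * 100`, where the
#' extrema are, by default, each pixel's own minimum and maximum over all
#' valid time steps (the multi-year climatology used by operational VCI
#' products); `scope = "global"` instead uses the extrema over all pixels
#' and periods. Pixels with fewer than two distinct valid values are
#' invalid.
#'
#' @param ndvi A [raster_cube()] of NDVI (valid values in \[-1, 1\]).
#' @param scope `"pixel"` (default) or `"global"` extrema.
#' @return A [raster_cube()] with values in \[0, 100\].
#' @export
compute_vci <- function(ndvi, scope = c("pixel", "global")) {
  scaled_extreme_index(ndvi, invert = FALSE, scope = scope)
}

#' Thermal Condition Index from an LST cube
#'
#' `TCI = (LST_MAX - LST) / (LST_MAX - LST_MIN) * 100`: the hottest
#' observation maps to 0 (maximal thermal stress) and the coolest to 100.
#' Extrema scope as in [compute_vci()].
#'
#' @param lst A [raster_cube()] of land surface temperature.
#' @inheritParams compute_vci
#' @return A [raster_cube()] with values in \[0, 100\].
#' @export
compute_tci <- function(lst, scope = c("pixel", "global")) {
  scaled_extreme_index(lst, invert = TRUE, scope = scope)
}

# Normalize a weight field (scalar, matrix, or contribution map) to a
# per-pixel matrix plus validity, checked against the grid.
resolve_weights <- function(weights, grid) {
  if (inherits(weights, "contribution_map")) {
    return(list(a = weights$a_opt, ok = weights$valid))
  }
  if (is.numeric(weights) && length(weights) == 1L) {
    if (is.na(weights) || weights < 0 || weights > 1)
      stop("weight must lie in [0, 1]")
    return(list(a = matrix(weights, grid$n_rows, grid$n_cols),
                ok = matrix(TRUE, grid$n_rows, grid$n_cols)))
  }
  if (is.matrix(weights)) {
    if (nrow(weights) != grid$n_rows || ncol(weights) != grid$n_cols)
      stop("per-pixel weights must match the cube grid (",
           grid$n_rows, " x ", grid$n_cols, ")")
    ok <- is.finite(weights)
    if (any(weights[ok] < 0 | weights[ok] > 1))
      stop("weights must lie in [0, 1]")
    return(list(a = weights, ok = ok))
  }
  stop("'weights' must be a scalar in [0, 1], a matrix, or a contribution_map")
}

#' Vegetation Health Index as a weighted VCI/TCI blend
#'
#' `VHI = a * VCI + (1 - a) * TCI` cellwise. The original index uses
#' `a = 0.5` (equal contributions); a per-pixel weight matrix or a
#' [contribution map][optimize_contribution()] yields the optimized index.
#'
#' @param vci,tci [raster_cube()]s on one grid and time axis, values in
#'   \[0, 100\].
#' @param weights Scalar in \[0, 1\], per-pixel matrix, or
#'   `contribution_map`. Default 0.5.
#' @return A [raster_cube()] of VHI, valid where both inputs (and the
#'   weight) are valid.
#' @export
compute_vhi <- function(vci, tci, weights = 0.5) {
  stopifnot(inherits(vci, "raster_cube"), inherits(tci, "raster_cube"))
  check_aligned(vci, tci)
  w <- resolve_weights(weights, vci$grid)
  nt <- nrow(vci$times)
  a <- aperm(array(w$a, c(dim(w$a), nt)), c(3L, 1L, 2L))
  wok <- aperm(array(w$ok, c(dim(w$ok), nt)), c(3L, 1L, 2L))
  ok <- vci$valid & tci$valid & wok
  vals <- a * vci$values + (1 - a) * tci$values
  vals[!ok] <- NA_real_
  raster_cube(vals, vci$times, vci$grid, ok)
}

#' The seven-level VHI drought classification
#'
#' @return A data frame with columns `code` (1-7), `label`, `lower`,
#'   `upper`: Extremely dry \[0, 10\], Severely dry (10, 20\], Moderately
#'   dry (20, 30\], Mild dry (30, 40\], Normal (40, 50\], Good (50, 60\],
#'   Excellent (60, 100\]. The intervals partition \[0, 100\].
#' @export
vhi_classes <- function() {
  data.frame(
    code = 1:7,
    label = c("ExtremelyDry", "SeverelyDry", "ModeratelyDry", "MildDry",
              "Normal", "Good", "Excellent"),
    lower = c(0, 10, 20, 30, 40, 50, 60),
    upper = c(10, 20, 30, 40, 50, 60, 100)
  )
}

#' Classify VHI values into drought classes
#'
#' Maps each VHI value in \[0, 100\] to one of the seven classes of
#' [vhi_classes()]; the first interval is closed on both ends, the rest are
#' left-open.
#'
#' @param vhi_value Numeric vector of VHI values in \[0, 100\].
#' @return Factor with the seven class labels (dry to healthy).
#' @export
classify_vhi <- function(vhi_value) {
  v <- as.numeric(vhi_value)
  bad <- !is.na(v) & (v < 0 | v > 100)
  if (any(bad))
    stop("VHI values outside [0, 100]: ", paste(utils::head(v[bad], 3L), collapse = ", "))
  cls <- vhi_classes()
  cut(v, breaks = c(cls$lower, 100), labels = cls$label,
      include.lowest = TRUE, right = TRUE)
}

#' Flag drought pixels by VHI threshold
#'
#' Marks cells whose VHI falls at or below `threshold` (default 40, the
#' upper bound of the Mild dry class). With `inclusive = FALSE` a value
#' exactly at the threshold counts as non-drought instead.
#'
#' @param vhi A [raster_cube()] of VHI.
#' @param threshold Drought cutoff in (0, 100). Default 40.
#' @param inclusive Treat VHI exactly equal to `threshold` as drought
#'   (default `TRUE`, consistent with Mild dry = (30, 40\]).
#' @return A [raster_cube()] of logicals (`TRUE` = drought), invalid where
#'   the input is invalid.
#' @export
drought_mask <- function(vhi, threshold = 40, inclusive = TRUE) {
  stopifnot(inherits(vhi, "raster_cube"))
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 100)
    stop("'threshold' must lie in (0, 100)")
  flag <- if (inclusive) vhi$values <= threshold else vhi$values < threshold
  flag[!vhi$valid] <- NA
  raster_cube(flag, vhi$times, vhi$grid, vhi$valid)
}
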