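# First-difference detrending, Theil-Sen slopes, the Mann-Kendall trend
# test, and ordinary linear fits for index-vs-reference comparisons.

#' First-difference detrending
#'
#' Replaces a series by successive differences, `x[t] - x[t-1]`, removing
#' slow trends before correlating an index with a reference. For a cube the
#' difference is taken along the time axis; an output step is valid only
#' when both operands are valid, and the first time label is dropped.
#'
#' @param x Numeric series or a [raster_cube()] with at least 2 time steps.
#' @return Object of the same kind with one fewer time step.
#' @export
detrend_diff <- function(x) {
  if (inherits(x, "raster_cube")) {
    nt <- nrow(x$times)
    if (nt < 2L) stop("detrending needs at least 2 time steps")
    vals <- x$values[-1L, , , drop = FALSE] - x$values[-nt, , , drop = FALSE]
    ok <- x$valid[-1L, , , drop = FALSE] & x$valid[-nt, , , drop = FALSE]
    vals[!ok] <- NA_real_
    return(raster_cube(vals, x$times[-1L, , drop = FALSE], x$grid, ok))
  }
  if (length(x) < 2L) stop("detrending needs at least 2 time steps")
  diff(x)
}

#' Theil-Sen slope estimator
#'
#' Median of all pairwise slopes `(y[j] - y[i]) / (t[j] - t[i])`, `i < j`;
#' with an even number of pairs the mean of the two central slopes. Robust
#' to outliers and to up to ~29% contamination.
#'
#' @param y Numeric series; non-finite entries are dropped with their times.
#' @param times Observation times. Default `seq_along(y)`.
#' @return Slope in y-units per time unit, or `NA` when fewer than two
#'   valid points (or no distinct times) remain.
#' @export
theil_sen <- function(y, times = seq_along(y)) {
  if (length(y) != length(times)) stop("'y' and 'times' must have equal length")
  ok <- is.finite(y) & is.finite(times)
  y <- y[ok]; t_ <- times[ok]
  n <- length(y)
  if (n < 2L) return(NA_real_)
  dy <- outer(y, y, "-")
  dt <- outer(t_, t_, "-")
  keep <- lower.tri(dt) & dt != 0
  if (!any(keep)) return(NA_real_)
  stats::median(dy[keep] / dt[keep])
}

#' Mann-Kendall trend test
#'
#' Nonparametric monotone-trend test: `S` is the sum over all pairs
#' `i < j` of `sign(y[j] - y[i])`; its variance uses the tie-corrected
#' formula `(n(n-1)(2n+5) - sum t(t-1)(2t+5)) / 18` over tie groups of
#' size `t`; the normalized statistic applies a continuity correction of
#' one unit toward zero, and the p-value is two-sided normal.
#'
#' @param y Numeric series; non-finite entries are dropped.
#' @return List with `mk_s` (integer S), `mk_z`, `p_value`, and `n`. For
#'   `n < 4` the z and p entries are `NA` (too short for the normal
#'   approximation to mean anything); an all-tied series gives `S = 0`,
#'   `p = 1`.
#' @export
mann_kendall <- function(y) {
  y <- y[is.finite(y)]
  n <- length(y)
  if (n < 2L) return(list(mk_s = NA_integer_, mk_z = NA_real_,
                          p_value = NA_real_, n = n))
  sgn <- sign(outer(y, y, "-"))
  s <- sum(sgn[lower.tri(sgn)])
  if (n < 4L) return(list(mk_s = as.integer(s), mk_z = NA_real_,
                          p_value = NA_real_, n = n))
  ties <- table(y)
  ties <- ties[ties > 1L]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (var_s <= 0) return(list(mk_s = as.integer(s), mk_z = 0,
                              p_value = 1, n = n))
  z <- if (s > 0) (s - 1) / sqrt(var_s) else if (s < 0) (s + 1) / sqrt(var_s) else 0
  p <- 2 * stats::pnorm(-abs(z))
  list(mk_s = as.integer(s), mk_z = z, p_value = p, n = n)
}

#' Per-pixel trend maps
#'
#' Theil-Sen slope and Mann-Kendall p-value for every pixel's valid series.
#' Pixels with fewer than 4 valid steps are invalid.
#'
#' @param cube A [raster_cube()] with at least 4 time steps.
#' @param times Numeric time coordinates for the slopes; defaults to
#'   decimal years, so slopes come out in index units per year.
#' @return List with matrices `slope`, `mk_z`, `p_value`, and a logical
#'   `valid`.
#' @export
trend_map <- function(cube, times = NULL) {
  stopifnot(inherits(cube, "raster_cube"))
  if (nrow(cube$times) < 4L) stop("trend mapping needs at least 4 time steps")
  if (is.null(times)) {
    tt <- cube$times
    times <- tt$year +
      (if ("month" %in% names(tt)) (tt$month - 1) / 12 else 0) +
      (if ("week" %in% names(tt)) (tt$week - 1) / 52 else 0)
  }
  m <- cube_matrices(cube)
  v <- m$values; v[!m$valid] <- NA_real_
  np <- ncol(v)
  slope <- z <- p <- rep(NA_real_, np)
  ok <- rep(FALSE, np)
  for (j in seq_len(np)) {
    yj <- v[, j]
    if (sum(is.finite(yj)) < 4L) next
    slope[j] <- theil_sen(yj, times)
    mk <- mann_kendall(yj)
    z[j] <- mk$mk_z; p[j] <- mk$p_value
    ok[j] <- TRUE
  }
  shp <- c(cube$grid$n_rows, cube$grid$n_cols)
  list(slope = matrix(slope, shp[1L], shp[2L]),
       mk_z = matrix(z, shp[1L], shp[2L]),
       p_value = matrix(p, shp[1L], shp[2L]),
       valid = matrix(ok, shp[1L], shp[2L]))
}

#' Ordinary least-squares fit of y on x
#'
#' Slope, intercept, Pearson correlation, coefficient of determination, and
#' the two-sided p-value of the slope (t-distribution, n - 2 degrees of
#' freedom), as printed on index-versus-reference scatter panels.
#'
#' @param x,y Paired numeric series; non-finite pairs are dropped.
#' @return A `fit_result`: list with `slope`, `intercept`, `r`, `r2`,
#'   `p_value`, `n`. All-`NA` when fewer than 3 pairs remain or x is
#'   constant.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  empty <- structure(list(slope = NA_real_, intercept = NA_real_,
                          r = NA_real_, r2 = NA_real_, p_value = NA_real_,
                          n = n), class = "fit_result")
  if (n < 3L || stats::sd(x) == 0) return(empty)
  fit <- stats::lm(y ~ x)
  # an exact line is a legitimate input here; silence the perfect-fit note
  co <- suppressWarnings(summary(fit))$coefficients
  r <- stats::cor(x, y)
  structure(list(slope = unname(co["x", "Estimate"]),
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 r = r, r2 = r^2,
                 p_value = unname(co["x", "Pr(>|t|)"]),
                 n = n),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit: y = %.4f x + %.4f  (r = %.4f, r2 = %.4f, p = %.3g, n = %d)\n",
              x$slope, x$intercept, x$r, x$r2, x$p_value, x$n))
  invisible(x)
}
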