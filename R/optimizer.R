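# Per-pixel estimation of the VCI contribution weight by grid search over
# candidate weights, maximizing Pearson correlation of the weighted VHI
# with a reference drought-index series.

#' The candidate grid of contribution weights
#'
#' The default grid steps from 0.02 to 0.98 in increments of 0.02 — exactly
#' 49 candidates, deliberately excluding the endpoints (a pure-VCI or
#' pure-TCI index). Note the equal-weight value 0.5 is the 25th candidate.
#'
#' @param step Grid increment in (0, 0.5). Default 0.02.
#' @return Strictly increasing numeric vector of weights in (0, 1).
#' @export
candidate_grid <- function(step = 0.02) {
  if (!is.finite(step) || step <= 0 || step >= 0.5)
    stop("'step' must lie in (0, 0.5)")
  n <- round(1 / step) - 1L
  a <- step * seq_len(n)
  a[a > 0 & a < 1]
}

#' Pearson product-moment correlation with pairwise-valid filtering
#'
#' Returns `NA` (rather than erroring) when fewer than `min_n` pairwise
#' finite observations remain or when either filtered series is constant,
#' so callers can mark the pixel invalid.
#'
#' @param x,y Numeric series of equal length; `NA`/non-finite entries are
#'   dropped pairwise.
#' @param min_n Minimum number of paired observations. Default 3.
#' @return Correlation in \[-1, 1\], or `NA`.
#' @export
pearson_r <- function(x, y, min_n = 3L) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < min_n) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Correlation profile of one pixel across candidate weights
#'
#' For each candidate weight `a`, forms the blended series
#' `a * vci + (1 - a) * tci` over the time steps where all three series are
#' valid and correlates it with the reference series.
#'
#' @param vci,tci,ref Time-aligned numeric series for one pixel.
#' @param candidates Candidate weights, see [candidate_grid()].
#' @param min_overlap Minimum number of jointly valid time steps; below it
#'   the whole profile is `NA`. Default 10.
#' @return Named numeric vector, one correlation (or `NA`) per candidate.
#' @export
correlation_profile <- function(vci, tci, ref, candidates = candidate_grid(),
                                min_overlap = 10L) {
  if (length(vci) != length(tci) || length(vci) != length(ref))
    stop("series must have equal length")
  ok <- is.finite(vci) & is.finite(tci) & is.finite(ref)
  r <- rep(NA_real_, length(candidates))
  names(r) <- format(candidates)
  if (sum(ok) >= max(3L, min_overlap)) {
    v <- vci[ok]; t_ <- tci[ok]; y <- ref[ok]
    for (i in seq_along(candidates)) {
      a <- candidates[i]
      r[i] <- pearson_r(a * v + (1 - a) * t_, y, min_n = 3L)
    }
  }
  r
}

#' Select the optimal weight from a correlation profile
#'
#' Picks the candidate with the largest signed correlation; exact ties
#' resolve to the smallest candidate weight. Profiles with no defined entry
#' yield `NA` (an invalid pixel).
#'
#' @param profile Correlations per candidate, as from
#'   [correlation_profile()].
#' @param candidates The matching candidate weights.
#' @return List with `a_opt` and `r_max` (both `NA` if undefined).
#' @export
select_a_opt <- function(profile, candidates = candidate_grid()) {
  if (length(profile) != length(candidates))
    stop("profile and candidate grid lengths differ")
  if (all(is.na(profile))) return(list(a_opt = NA_real_, r_max = NA_real_))
  i <- which.max(profile)  # first (= smallest-a) maximum on ties
  list(a_opt = candidates[i], r_max = unname(profile[i]))
}

#' Estimate the optimal VCI contribution weight per pixel
#'
#' For every pixel, runs the grid search of [correlation_profile()] against
#' the reference drought-index cube and selects the weight maximizing the
#' Pearson correlation ([select_a_opt()]). Pixels with fewer than
#' `min_overlap` jointly valid time steps, or whose series are degenerate
#' (constant), are invalid. The maximum of the signed correlation is used;
#' pixels whose best correlation is negative are retained and can be
#' screened via `r_max`.
#'
#' @param vci,tci,ref [raster_cube()]s on one grid and time axis (bring the
#'   reference onto the target grid first with [resample_nearest()] /
#'   [aggregate_time()]).
#' @param min_overlap Minimum jointly valid time steps per pixel. Default 10.
#' @param candidates Candidate weights. Default [candidate_grid()].
#' @return A `contribution_map`: list with the grid, per-pixel matrices
#'   `a_opt`, `r_max`, `n_used`, a `valid` mask, and the candidate grid.
#' @export
optimize_contribution <- function(vci, tci, ref, min_overlap = 10L,
                                  candidates = candidate_grid()) {
  stopifnot(inherits(vci, "raster_cube"), inherits(tci, "raster_cube"),
            inherits(ref, "raster_cube"))
  check_aligned(vci, tci)
  check_aligned(vci, ref, what = "grid")
  if (nrow(ref$times) != nrow(vci$times))
    stop("reference cube has a different number of time steps")
  min_overlap <- max(3L, as.integer(min_overlap))

  mv <- cube_matrices(vci); mt <- cube_matrices(tci); my <- cube_matrices(ref)
  M <- mv$valid & mt$valid & my$valid
  nt <- nrow(M); np <- ncol(M)
  n <- colSums(M)
  V <- mv$values; T_ <- mt$values; Y <- my$values
  V[!M] <- 0; T_[!M] <- 0; Y[!M] <- 0

  nn <- pmax(n, 1L)
  ym <- colSums(Y) / nn
  Yc <- (Y - rep(ym, each = nt)) * M
  Syy <- colSums(Yc * Yc)

  best_r <- rep(-Inf, np)
  best_a <- rep(NA_real_, np)
  eligible <- n >= min_overlap & Syy > 1e-10
  for (a in candidates) {              # ascending, so ties keep smallest a
    X <- a * V + (1 - a) * T_
    xm <- colSums(X) / nn
    Xc <- (X - rep(xm, each = nt)) * M
    Sxx <- colSums(Xc * Xc)
    r <- colSums(Xc * Yc) / sqrt(Sxx * Syy)
    r[Sxx <= 1e-10] <- NA_real_
    upd <- eligible & !is.na(r) & r > best_r
    best_r[upd] <- r[upd]
    best_a[upd] <- a
  }
  ok <- !is.na(best_a)
  best_r[!ok] <- NA_real_
  shape <- c(vci$grid$n_rows, vci$grid$n_cols)
  structure(
    list(grid = vci$grid,
         a_opt = matrix(best_a, shape[1L], shape[2L]),
         r_max = matrix(best_r, shape[1L], shape[2L]),
         n_used = matrix(as.integer(n), shape[1L], shape[2L]),
         valid = matrix(ok, shape[1L], shape[2L]),
         candidates = candidates),
    class = "contribution_map"
  )
}

#' @export
print.contribution_map <- function(x, ...) {
  cat(sprintf("contribution_map: %d x %d grid, %d candidates, %.1f%% valid pixels\n",
              x$grid$n_rows, x$grid$n_cols, length(x$candidates),
              100 * mean(x$valid)))
  if (any(x$valid))
    cat(sprintf("  a_opt: median %.2f  |  r_max: median %.3f\n",
                stats::median(x$a_opt[x$valid]), stats::median(x$r_max[x$valid])))
  invisible(x)
}

#' Optimized VHI from a contribution map
#'
#' Applies the per-pixel optimal weights: `VHI_opt = a_opt * VCI +
#' (1 - a_opt) * TCI`. Invalid wherever the contribution map is invalid.
#'
#' @inheritParams compute_vhi
#' @param cmap A `contribution_map` from [optimize_contribution()].
#' @return A [raster_cube()] of the optimized VHI.
#' @export
compute_vhi_opt <- function(vci, tci, cmap) {
  stopifnot(inherits(cmap, "contribution_map"))
  if (!grid_equal(vci$grid, cmap$grid))
    stop("contribution map grid does not match the cubes")
  compute_vhi(vci, tci, weights = cmap)
}

#' Fractions of VCI- and TCI-dominated pixels
#'
#' A pixel is TCI-dominated when `a_opt < 0.5` and VCI-dominated when
#' `a_opt > 0.5`. Pixels whose optimum lands exactly on the equal-weight
#' candidate 0.5 count as neither, so the two fractions can sum to slightly
#' less than 1.
#'
#' @param cmap A `contribution_map`.
#' @return List with `frac_tci_dominated` and `frac_vci_dominated`.
#' @export
dominance_summary <- function(cmap) {
  stopifnot(inherits(cmap, "contribution_map"))
  a <- cmap$a_opt[cmap$valid]
  if (length(a) == 0L) stop("contribution map has no valid pixels")
  list(frac_tci_dominated = mean(a < 0.5),
       frac_vci_dominated = mean(a > 0.5))
}

#' Write a contribution map as GeoTIFF files
#'
#' Writes `a_opt.tif` and `r_max.tif` (six-decimal values, -9999 nodata)
#' into `out_dir`.
#'
#' @param cmap A `contribution_map`.
#' @param out_dir Output directory.
#' @param nodata Nodata code. Default -9999.
#' @return Character vector of the two paths.
#' @export
write_contribution_map <- function(cmap, out_dir, nodata = -9999) {
  stopifnot(inherits(cmap, "contribution_map"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory '", out_dir, "'")
  paths <- file.path(out_dir, c("a_opt.tif", "r_max.tif"))
  for (i in 1:2) {
    m <- round(list(cmap$a_opt, cmap$r_max)[[i]], 6L)
    m[!cmap$valid] <- nodata
    write_geotiff(paths[i], m, cmap$grid, nodata = nodata)
  }
  paths
}
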