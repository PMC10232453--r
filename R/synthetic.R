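# Synthetic co-registered VCI/TCI/reference cubes with known per-pixel
# mixing weights, injected drought events, and optional linear trends, so
# the whole pipeline is testable without satellite archives.

#' Configure a synthetic scene
#'
#' Describes a scene of co-registered annual VCI, TCI, and reference
#' drought-index cubes generated from two independent standard-normal
#' latent series per pixel (a vegetation channel and a thermal channel).
#' The reference series is the `a_true`-weighted blend of the two finished
#' indices plus Gaussian noise, so the contribution optimizer has a known,
#' exact target.
#' Defaults mirror the conditions of a 41-year (1981-2021) annual
#' calibration on a small tile.
#'
#' @param n_rows,n_cols Grid dimensions. Default 32 x 32.
#' @param n_years Series length. Default 41.
#' @param start_year First year. Default 1981.
#' @param a_true True per-pixel VCI weight: `"random"` (uniform on
#'   \[0.02, 0.98\]), `"gradient"` (0.1 to 0.9 across columns), a scalar,
#'   or a full matrix.
#' @param snr Ratio of the blended-signal standard deviation to the noise
#'   standard deviation in the reference series; `Inf` for noise-free.
#'   Default 10.
#' @param drought_events List of injected events, each a list with `year`,
#'   `bbox` (map coordinates), `severity` (VHI units removed at the
#'   equal-weight index), and optional `continent`. The default injects a
#'   severe, a moderate, and a null event, exercising all three detection
#'   scores.
#' @param severity_mode `"channel"` (default) splits an event's severity
#'   across the vegetation and thermal channels in proportion to each
#'   pixel's true weights — drought expresses through the channel that
#'   actually drives the pixel, and an equal-weight VHI loses exactly
#'   `severity` units; `"flat"` subtracts `severity` from both indices.
#' @param trend_slope Linear trend (index units per year) added to both
#'   indices. Default 0.
#' @param ar1 Lag-one autocorrelation of the latent series. Default 0.
#' @param seed Integer RNG seed; the same scenario and seed reproduce the
#'   scene bit for bit.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_rows = 32L, n_cols = 32L, n_years = 41L,
                               start_year = 1981L, a_true = "random",
                               snr = 10, drought_events = NULL,
                               severity_mode = c("channel", "flat"),
                               trend_slope = 0, ar1 = 0, seed = 42L) {
  if (n_rows < 1L || n_cols < 1L) stop("grid dimensions must be >= 1")
  if (n_years < 3L) stop("'n_years' must be >= 3")
  if (is.na(snr) || snr <= 0) stop("'snr' must be positive")
  if (abs(ar1) >= 1) stop("'ar1' must lie in (-1, 1)")
  severity_mode <- match.arg(severity_mode)
  if (is.null(drought_events))
    drought_events <- default_drought_events(n_rows, n_cols, n_years, start_year)
  for (e in drought_events) {
    if (!all(c("year", "bbox", "severity") %in% names(e)))
      stop("each drought event needs 'year', 'bbox', and 'severity'")
    if (e$year < start_year || e$year > start_year + n_years - 1L)
      stop("event year ", e$year, " is outside the simulated span")
    if (e$severity < 0) stop("event severity must be >= 0")
  }
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 n_years = as.integer(n_years),
                 start_year = as.integer(start_year),
                 a_true = a_true, snr = snr,
                 drought_events = drought_events,
                 severity_mode = severity_mode,
                 trend_slope = trend_slope, ar1 = ar1,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

# Three default events on the scene's unit grid (origin (0, n_rows), 1-unit
# pixels): one severe enough to flag essentially the whole region, one
# moderate (roughly half to three-quarters flagged), and one null control.
default_drought_events <- function(n_rows, n_cols, n_years, start_year) {
  h <- max(1L, n_rows %/% 3L); w <- max(1L, n_cols %/% 3L)
  yr <- function(frac) start_year + as.integer(round(frac * (n_years - 1L)))
  list(
    list(year = yr(0.35), bbox = c(0, n_rows - h, w, n_rows),
         severity = 50, continent = "west"),
    list(year = yr(0.55), bbox = c(n_cols - w, 0, n_cols, h),
         severity = 18, continent = "east"),
    list(year = yr(0.75), bbox = c(0, 0, w, h),
         severity = 0, continent = "west")
  )
}

resolve_a_true <- function(a_true, n_rows, n_cols) {
  if (is.character(a_true)) {
    a_true <- match.arg(a_true, c("random", "gradient"))
    if (a_true == "random")
      return(matrix(stats::runif(n_rows * n_cols, 0.02, 0.98), n_rows, n_cols))
    return(matrix(rep(seq(0.1, 0.9, length.out = n_cols), each = n_rows),
                  n_rows, n_cols))
  }
  if (is.numeric(a_true) && length(a_true) == 1L)
    a_true <- matrix(a_true, n_rows, n_cols)
  if (!is.matrix(a_true) || nrow(a_true) != n_rows || ncol(a_true) != n_cols)
    stop("'a_true' must be \"random\", \"gradient\", a scalar, or a full matrix")
  if (any(a_true < 0 | a_true > 1)) stop("'a_true' must lie in [0, 1]")
  a_true
}

# Stationary AR(1) innovations matrix (nt x np), unit marginal variance.
latent_matrix <- function(nt, np, ar1) {
  e <- matrix(stats::rnorm(nt * np), nt, np)
  if (ar1 == 0) return(e)
  x <- e
  x[1L, ] <- e[1L, ]
  for (t_ in 2:nt) x[t_, ] <- ar1 * x[t_ - 1L, ] + sqrt(1 - ar1^2) * e[t_, ]
  x
}

# Per-pixel min-max scaling of a (nt x np) matrix into [lo, hi].
scale_to_range <- function(m, lo, hi) {
  mn <- apply(m, 2L, min); mx <- apply(m, 2L, max)
  sweep(sweep(m, 2L, mn), 2L, (mx - mn) / (hi - lo), "/") + lo
}

#' Generate the cubes of a synthetic scene
#'
#' Draws two independent standard-normal latent series per pixel, min-max
#' scales each into \[0, 100\] (mirroring how VCI and TCI are built from
#' their own historical extrema), adds any configured trend, injects the
#' drought events, and finally blends the finished indices with the true
#' weights plus Gaussian noise at the scenario's signal-to-noise ratio to
#' form the reference index. Deterministic under the scenario seed.
#'
#' @param scenario A [synthetic_scenario()].
#' @return List with [raster_cube()]s `vci`, `tci`, `ref`, and `truth`
#'   (list with the `a_true` matrix, `trend_slope`, and an `events` data
#'   frame holding each event's geometry, severity, and the detection score
#'   expected from the true-weight VHI).
#' @export
generate_cubes <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$seed)
  nr <- scenario$n_rows; nc <- scenario$n_cols
  nt <- scenario$n_years; np <- nr * nc
  grid <- grid_spec(nr, nc)
  years <- scenario$start_year + seq_len(nt) - 1L

  a_true <- resolve_a_true(scenario$a_true, nr, nc)
  av <- as.vector(a_true)
  V <- latent_matrix(nt, np, scenario$ar1)
  T_ <- latent_matrix(nt, np, scenario$ar1)

  margin <- abs(scenario$trend_slope) * (nt - 1) / 2
  if (margin >= 50) stop("'trend_slope' too steep for a [0, 100] index")
  vci <- scale_to_range(V, margin, 100 - margin)
  tci <- scale_to_range(T_, margin, 100 - margin)
  if (scenario$trend_slope != 0) {
    tr <- scenario$trend_slope * (seq_len(nt) - (nt + 1) / 2)
    vci <- vci + tr
    tci <- tci + tr
  }

  # Inject events. In channel mode the vegetation index loses
  # 2 * severity * a_true and the thermal index 2 * severity * (1 - a_true),
  # so the equal-weight blend loses exactly 'severity' while any blend
  # closer to the true weights loses at least as much.
  for (e in scenario$drought_events) {
    if (e$severity == 0) next
    ev <- drought_event("tmp", e$year, bbox = e$bbox)
    px <- which(as.vector(region_mask(ev, grid)))
    ti <- match(e$year, years)
    if (scenario$severity_mode == "channel") {
      vci[ti, px] <- vci[ti, px] - 2 * e$severity * av[px]
      tci[ti, px] <- tci[ti, px] - 2 * e$severity * (1 - av[px])
    } else {
      vci[ti, px] <- vci[ti, px] - e$severity
      tci[ti, px] <- tci[ti, px] - e$severity
    }
  }
  vci <- pmin(pmax(vci, 0), 100)
  tci <- pmin(pmax(tci, 0), 100)

  # The reference index is the true-weight blend of the finished indices
  # plus Gaussian noise at the configured signal-to-noise ratio. Pearson
  # correlation is affine-invariant, so its absolute units are immaterial;
  # building it from the scaled indices (rather than the raw latents) is
  # what makes the optimizer's target exact: at infinite snr the best
  # candidate weight is the grid point nearest a_true at every pixel.
  mix <- sweep(vci, 2L, av, "*") + sweep(tci, 2L, 1 - av, "*")
  if (is.finite(scenario$snr)) {
    noise_sd <- apply(mix, 2L, stats::sd) / scenario$snr
    ref <- mix + matrix(stats::rnorm(nt * np), nt, np) * rep(noise_sd, each = nt)
  } else {
    ref <- mix
  }

  ok <- matrix(TRUE, nt, np)
  cubes <- list(
    vci = cube_from_matrices(vci, ok, years, grid),
    tci = cube_from_matrices(tci, ok, years, grid),
    ref = cube_from_matrices(ref, matrix(TRUE, nt, np), years, grid)
  )
  truth_vhi <- compute_vhi(cubes$vci, cubes$tci, weights = a_true)
  ev_rows <- lapply(seq_along(scenario$drought_events), function(i) {
    e <- scenario$drought_events[[i]]
    de <- drought_event(sprintf("ev%02d", i), e$year, bbox = e$bbox,
                        continent = if (is.null(e$continent)) NA_character_
                                    else e$continent)
    sc <- score_event(truth_vhi, de)
    data.frame(event_id = de$event_id, year = e$year,
               min_x = e$bbox[1L], min_y = e$bbox[2L],
               max_x = e$bbox[3L], max_y = e$bbox[4L],
               severity = e$severity, continent = de$continent,
               expected_fraction = sc$fraction, expected_score = sc$score)
  })
  cubes$truth <- list(a_true = a_true,
                      trend_slope = scenario$trend_slope,
                      events = do.call(rbind, ev_rows))
  cubes
}

#' Event catalog of a synthetic scene
#'
#' Returns the scene's injected events as [drought_event()]s together with
#' the truth table (expected fraction and score of each event under the
#' true-weight VHI). Severities in the default scenario exercise all three
#' score levels.
#'
#' @param scenario A [synthetic_scenario()], or the result of
#'   [generate_cubes()] (to avoid regenerating).
#' @return List with `events` (list of [drought_event()]) and `table` (the
#'   truth data frame).
#' @export
generate_event_catalog <- function(scenario) {
  sim <- if (inherits(scenario, "synthetic_scenario")) generate_cubes(scenario)
         else scenario
  if (is.null(sim$truth))
    stop("'scenario' must be a synthetic_scenario or the output of generate_cubes()")
  tab <- sim$truth$events
  if (is.null(tab) || nrow(tab) == 0L) stop("scenario has no drought events")
  events <- lapply(seq_len(nrow(tab)), function(i)
    drought_event(tab$event_id[i], tab$year[i],
                  bbox = c(tab$min_x[i], tab$min_y[i], tab$max_x[i], tab$max_y[i]),
                  continent = tab$continent[i]))
  list(events = events, table = tab)
}

#' Write a synthetic event catalog to CSV
#'
#' @param catalog Output of [generate_event_catalog()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(catalog, path) {
  utils::write.csv(catalog$table, path, row.names = FALSE, na = "")
  invisible(path)
}
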