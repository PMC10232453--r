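# Scoring recorded drought events against a VHI cube and computing
# detection efficiency (DTE).

#' A recorded drought event
#'
#' One catalog record: an identifier, the event year, and its region,
#' given either as a bounding box in map coordinates or as a per-pixel
#' logical mask on the scoring grid. Real-world catalogs (EM-DAT style)
#' locate events by country or place name; translating those into geometry
#' is up to the user — this package consumes geometry only.
#'
#' @param event_id Text identifier.
#' @param year Integer event year.
#' @param bbox Numeric `c(min_x, min_y, max_x, max_y)` in map coordinates,
#'   or `NULL` when `mask` is given. Pixel centers inside the box (half-open
#'   on the max edges) belong to the region.
#' @param mask Logical matrix (`n_rows` x `n_cols`) marking the region, or
#'   `NULL`.
#' @param continent Optional text tag used for stratified reports.
#' @return An object of class `drought_event`.
#' @export
drought_event <- function(event_id, year, bbox = NULL, mask = NULL,
                          continent = NA_character_) {
  if (is.null(bbox) == is.null(mask))
    stop("give exactly one of 'bbox' or 'mask'")
  if (!is.null(bbox)) {
    bbox <- as.numeric(bbox)
    if (length(bbox) != 4L || any(!is.finite(bbox)))
      stop("'bbox' must be c(min_x, min_y, max_x, max_y)")
    if (bbox[1L] >= bbox[3L] || bbox[2L] >= bbox[4L])
      stop("'bbox' must have min < max on both axes")
  }
  if (!is.null(mask) && !is.logical(mask))
    stop("'mask' must be a logical matrix")
  structure(list(event_id = as.character(event_id), year = as.integer(year),
                 bbox = bbox, mask = mask,
                 continent = as.character(continent)),
            class = "drought_event")
}

#' Region mask of an event on a grid
#'
#' For a bounding-box event, pixels whose centers satisfy
#' `min_x <= x < max_x` and `min_y <= y < max_y` belong to the region; a
#' mask event returns its mask unchanged (after a dimension check).
#'
#' @param event A [drought_event()].
#' @param grid A [grid_spec()].
#' @return Logical matrix (`n_rows` x `n_cols`).
#' @export
region_mask <- function(event, grid) {
  stopifnot(inherits(event, "drought_event"), inherits(grid, "grid_spec"))
  if (!is.null(event$mask)) {
    if (nrow(event$mask) != grid$n_rows || ncol(event$mask) != grid$n_cols)
      stop("mask of event '", event$event_id, "' does not match the grid")
    m <- event$mask
  } else {
    ctr <- grid_centers(grid)
    inx <- ctr$x >= event$bbox[1L] & ctr$x < event$bbox[3L]
    iny <- ctr$y >= event$bbox[2L] & ctr$y < event$bbox[4L]
    m <- outer(iny, inx, "&")
  }
  if (!any(m))
    stop("region of event '", event$event_id, "' does not intersect the grid")
  m
}

#' Score one drought event against an annual VHI cube
#'
#' Computes the fraction of valid region pixels flagged as drought
#' ([drought_mask()], VHI at or below `threshold`) in the event year, and
#' assigns the three-level score: 1 when the fraction exceeds 0.8, 0.5 when
#' it exceeds 0.4, and 0 otherwise (boundaries are strict: a fraction of
#' exactly 0.8 scores 0.5, exactly 0.4 scores 0). Only valid pixels enter
#' the denominator.
#'
#' @param vhi_annual An annual [raster_cube()] of VHI.
#' @param event A [drought_event()] whose year is in the cube.
#' @param threshold Drought cutoff. Default 40.
#' @param inclusive Passed to [drought_mask()]. Default `TRUE`.
#' @return An `event_score`: list with `event_id`, `year`, `continent`,
#'   `n_region_pixels`, `n_drought_pixels`, `fraction`, `score`.
#' @export
score_event <- function(vhi_annual, event, threshold = 40, inclusive = TRUE) {
  stopifnot(inherits(vhi_annual, "raster_cube"), inherits(event, "drought_event"))
  ti <- which(vhi_annual$times$year == event$year)
  if (length(ti) != 1L)
    stop("year ", event$year, " of event '", event$event_id,
         "' is not in the cube's time axis")
  region <- region_mask(event, vhi_annual$grid)
  ok <- vhi_annual$valid[ti, , ] & region
  n_region <- sum(ok)
  if (n_region == 0L)
    stop("event '", event$event_id, "' has no valid pixels in its region")
  v <- vhi_annual$values[ti, , ]
  flagged <- if (inclusive) v <= threshold else v < threshold
  n_drought <- sum(flagged & ok, na.rm = TRUE)
  fraction <- n_drought / n_region
  score <- if (fraction > 0.8) 1 else if (fraction > 0.4) 0.5 else 0
  structure(list(event_id = event$event_id, year = event$year,
                 continent = event$continent,
                 n_region_pixels = n_region, n_drought_pixels = n_drought,
                 fraction = fraction, score = score),
            class = "event_score")
}

scores_to_df <- function(scores) {
  do.call(rbind, lapply(scores, function(s)
    data.frame(event_id = s$event_id, year = s$year, continent = s$continent,
               n_region_pixels = s$n_region_pixels,
               n_drought_pixels = s$n_drought_pixels,
               fraction = s$fraction, score = s$score)))
}

#' Drought detection efficiency from event scores
#'
#' `DTE = 100 * S / TDE`, where `S` is the sum of the per-event scores and
#' `TDE` the number of events. With `by = "year"` or `by = "continent"` a
#' stratified table of group-wise DTEs is attached.
#'
#' @param scores List of `event_score` objects (see [score_event()]).
#' @param by Optional grouping field: `"year"` or `"continent"`.
#' @return A `detection_report`: list with `scores` (data frame),
#'   `total_events`, `total_score`, `dte` (percent), and optionally
#'   `groups`.
#' @export
detection_efficiency <- function(scores, by = NULL) {
  if (inherits(scores, "event_score")) scores <- list(scores)
  if (length(scores) == 0L) stop("no events to evaluate")
  df <- scores_to_df(scores)
  out <- list(scores = df, total_events = nrow(df),
              total_score = sum(df$score),
              dte = 100 * sum(df$score) / nrow(df))
  if (!is.null(by)) {
    by <- match.arg(by, c("year", "continent"))
    g <- split(df$score, df[[by]])
    out$groups <- data.frame(
      group = names(g),
      n_events = vapply(g, length, 0L),
      total_score = vapply(g, sum, 0),
      dte = vapply(g, function(s) 100 * sum(s) / length(s), 0),
      row.names = NULL)
  }
  structure(out, class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("detection_report: %d events, total score %.1f, DTE %.2f%%\n",
              x$total_events, x$total_score, x$dte))
  if (!is.null(x$groups)) print(x$groups)
  invisible(x)
}

#' Compare the detection skill of two VHI cubes
#'
#' Scores the identical event list against both cubes (typically the
#' optimized and the equal-weight VHI) and reports both DTEs plus per-year
#' counts of detected events (score > 0) for histogram-style comparison.
#'
#' @param vhi_a,vhi_b Annual [raster_cube()]s on one grid and time axis.
#' @param events List of [drought_event()]s.
#' @param threshold,inclusive Passed to [score_event()].
#' @param by Optional stratification passed to [detection_efficiency()].
#' @return List with `report_a`, `report_b`, and `per_year` (data frame of
#'   observed and detected event counts per year).
#' @export
compare_indices <- function(vhi_a, vhi_b, events, threshold = 40,
                            inclusive = TRUE, by = NULL) {
  check_aligned(vhi_a, vhi_b)
  scores_a <- lapply(events, function(e)
    score_event(vhi_a, e, threshold = threshold, inclusive = inclusive))
  scores_b <- lapply(events, function(e)
    score_event(vhi_b, e, threshold = threshold, inclusive = inclusive))
  ra <- detection_efficiency(scores_a, by = by)
  rb <- detection_efficiency(scores_b, by = by)
  yrs <- sort(unique(vapply(events, function(e) e$year, 0L)))
  per_year <- data.frame(
    year = yrs,
    n_observed = vapply(yrs, function(y) sum(ra$scores$year == y), 0L),
    n_detected_a = vapply(yrs, function(y)
      sum(ra$scores$year == y & ra$scores$score > 0), 0L),
    n_detected_b = vapply(yrs, function(y)
      sum(rb$scores$year == y & rb$scores$score > 0), 0L))
  list(report_a = ra, report_b = rb, per_year = per_year)
}

#' Read a drought-event catalog from CSV
#'
#' Expected columns: `event_id`, `year`, `min_x`, `min_y`, `max_x`,
#' `max_y`, and optionally `continent`. (Longitude/latitude column aliases
#' `min_lon`/`min_lat`/`max_lon`/`max_lat` are accepted.)
#'
#' @param path CSV file path.
#' @return List of [drought_event()]s.
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  alias <- c(min_lon = "min_x", min_lat = "min_y",
             max_lon = "max_x", max_lat = "max_y")
  for (nm in names(alias))
    if (nm %in% names(df) && !alias[[nm]] %in% names(df))
      names(df)[names(df) == nm] <- alias[[nm]]
  need <- c("event_id", "year", "min_x", "min_y", "max_x", "max_y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("event catalog is missing columns: ", paste(miss, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    drought_event(df$event_id[i], df$year[i],
                  bbox = c(df$min_x[i], df$min_y[i], df$max_x[i], df$max_y[i]),
                  continent = if ("continent" %in% names(df))
                    df$continent[i] else NA_character_))
}

#' Write per-event scores and a summary row to CSV
#'
#' Appends one `DTE` row after the per-event rows; its `score` column holds
#' the detection efficiency in percent.
#'
#' @param report A `detection_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "detection_report"))
  df <- report$scores
  summary_row <- df[1L, ]
  summary_row[1L, ] <- NA
  summary_row$event_id <- "DTE"
  summary_row$score <- report$dte
  utils::write.csv(rbind(df, summary_row), path, row.names = FALSE, na = "")
  invisible(path)
}
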