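# Configuration-driven pipeline chaining the modules: preprocess ->
# indices -> weight optimization -> optimized VHI -> event detection ->
# trends, with a hashed output manifest for reproducibility checks.

PIPELINE_KEYS <- c(
  "scenario", "vci_dir", "tci_dir", "ref_dir", "events_csv", "out_dir",
  "years", "background_value", "threshold", "boundary_inclusive",
  "candidate_step", "min_overlap", "baseline_a", "do_detect", "do_trends",
  "log_level"
)

#' Build a pipeline configuration
#'
#' Either supply directories of per-year GeoTIFFs (`vci_dir`, `tci_dir`,
#' `ref_dir`, with `years` identifying the files as `*_{year}.tif`), or a
#' `scenario` (see [synthetic_scenario()]) to generate inputs. Unknown keys
#' are rejected. Defaults mirror the published method: candidate step 0.02,
#' drought threshold 40, equal-weight baseline 0.5.
#'
#' @param ... Configuration values; see `PIPELINE_KEYS` in the package
#'   source. `out_dir` is required.
#' @param file Optional YAML file to read the configuration from; values
#'   in `...` override it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- if (is.null(file)) list() else yaml::read_yaml(file)
  dots <- list(...)
  cfg[names(dots)] <- dots
  unknown <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  defaults <- list(background_value = -9999, threshold = 40,
                   boundary_inclusive = TRUE, candidate_step = 0.02,
                   min_overlap = 10L, baseline_a = 0.5,
                   do_detect = TRUE, do_trends = FALSE, log_level = "info")
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (is.null(cfg$out_dir)) stop("configuration needs 'out_dir'")
  has_dirs <- !is.null(cfg$vci_dir) && !is.null(cfg$tci_dir) && !is.null(cfg$ref_dir)
  if (is.null(cfg$scenario) && !has_dirs)
    stop("configuration needs either 'scenario' or vci_dir/tci_dir/ref_dir")
  if (!is.null(cfg$scenario) && !inherits(cfg$scenario, "synthetic_scenario"))
    cfg$scenario <- do.call(synthetic_scenario, cfg$scenario)
  structure(cfg, class = "pipeline_config")
}

pipe_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(format(Sys.time(), "%H:%M:%S "), ...)
}

run_stage <- function(name, cfg, expr) {
  pipe_log(cfg, "stage ", name)
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full VHI optimization pipeline
#'
#' Executes input loading (or synthetic generation), weight optimization,
#' optimized- and baseline-VHI synthesis, optional event detection and
#' trend mapping, writing all products under `out_dir` plus a JSON manifest
#' listing every file with its MD5 hash. Rerunning an identical
#' configuration reproduces identical hashes.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly: list with `files` (data frame of path
#'   and md5) and headline numbers (`dte_opt`, `dte_ori` when detection
#'   ran).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out) && !dir.create(out, recursive = TRUE))
    stop("cannot create output directory '", out, "'")

  events <- NULL
  if (!is.null(config$scenario)) {
    sim <- run_stage("simulate", config, generate_cubes(config$scenario))
    vci <- sim$vci; tci <- sim$tci; ref <- sim$ref
    cat_ <- generate_event_catalog(sim)
    events <- cat_$events
    run_stage("simulate", config,
              write_events_csv(cat_, file.path(out, "events.csv")))
  } else {
    load_dir <- function(dir, what) {
      pat <- if (is.null(config$years)) "_[0-9]{4}\\.tif$" else "\\.tif$"
      paths <- sort(list.files(dir, pattern = pat, full.names = TRUE))
      if (length(paths) == 0L) stop("no GeoTIFFs in ", what, " directory '", dir, "'")
      yrs <- if (!is.null(config$years)) as.integer(config$years) else
        as.integer(sub(".*_([0-9]{4})\\.tif$", "\\1", basename(paths)))
      if (anyNA(yrs)) stop("cannot parse years from file names in '", dir, "'")
      o <- order(yrs)
      read_cube(paths[o], yrs[o], background_value = config$background_value)
    }
    vci <- run_stage("read_vci", config, load_dir(config$vci_dir, "VCI"))
    tci <- run_stage("read_tci", config, load_dir(config$tci_dir, "TCI"))
    ref <- run_stage("read_ref", config, load_dir(config$ref_dir, "reference"))
    if (!grid_equal(ref$grid, vci$grid))
      ref <- run_stage("resample_ref", config, resample_nearest(ref, vci$grid))
    if (!is.null(config$events_csv))
      events <- run_stage("read_events", config, read_events_csv(config$events_csv))
  }

  cmap <- run_stage("optimize", config,
                    optimize_contribution(vci, tci, ref,
                                          min_overlap = config$min_overlap,
                                          candidates = candidate_grid(config$candidate_step)))
  run_stage("optimize", config, write_contribution_map(cmap, out))

  vhi_opt <- run_stage("vhi_opt", config, compute_vhi_opt(vci, tci, cmap))
  run_stage("vhi_opt", config, write_cube(vhi_opt, out, "VHIopt_{year}.tif"))
  vhi_ori <- run_stage("vhi_ori", config,
                       compute_vhi(vci, tci, weights = config$baseline_a))

  manifest <- list()
  if (isTRUE(config$do_detect) && !is.null(events)) {
    cmp <- run_stage("detect", config,
                     compare_indices(vhi_opt, vhi_ori, events,
                                     threshold = config$threshold,
                                     inclusive = config$boundary_inclusive))
    run_stage("detect", config, {
      write_report_csv(cmp$report_a, file.path(out, "detection_vhi_opt.csv"))
      write_report_csv(cmp$report_b, file.path(out, "detection_vhi_ori.csv"))
      utils::write.csv(cmp$per_year, file.path(out, "detection_per_year.csv"),
                       row.names = FALSE)
    })
    manifest$dte_opt <- cmp$report_a$dte
    manifest$dte_ori <- cmp$report_b$dte
  }
  if (isTRUE(config$do_trends)) {
    tm <- run_stage("trends", config, trend_map(vhi_opt))
    run_stage("trends", config, {
      slope <- round(tm$slope, 6L); slope[!tm$valid] <- -9999
      pv <- round(tm$p_value, 6L); pv[!tm$valid] <- -9999
      write_geotiff(file.path(out, "trend_slope.tif"), slope, vhi_opt$grid)
      write_geotiff(file.path(out, "trend_p.tif"), pv, vhi_opt$grid)
    })
  }

  files <- sort(setdiff(list.files(out, full.names = TRUE, recursive = TRUE),
                        file.path(out, "manifest.json")))
  manifest$files <- data.frame(path = basename(files),
                               md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipe_log(config, "wrote ", nrow(manifest$files), " files to ", out)
  invisible(manifest)
}
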