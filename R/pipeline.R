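#' Default pipeline configuration
#'
#' Nested configuration for [run_pipeline()], with every stage's defaults
#' matching the analysis settings: index factors (X_SAVI 0.5, X_TSAVI
#' 0.08, X_EVI 1, G 2.5, C1 6, C2 7.5; soil line a 1.2, b 0.04),
#' screening windows (8/16 days, cloud fraction < 0.20), quarterly
#' decomposition with period 4 and a 4-quarter rolling window, ADF on the
#' residual component, and the search grid [-0.3, 1] by 0.001.
#'
#' @param ... Named overrides, merged recursively into the defaults
#'   (e.g. `calibration = list(step = 0.01)`).
#' @param seed Integer seed driving the simulate stage.
#' @return A nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., seed = 1) {
  defaults <- list(
    seed = seed,
    simulate = list(enabled = TRUE, mean_lai = 5.5, seasonal_amplitude = 1,
                    trend_per_year = 0, noise_sd = 0.3, missing_prob = 0.1,
                    start_date = "2013-04-16", end_date = "2020-10-21",
                    scene_cadence_days = 8, lai_cadence_days = 4,
                    band_noise_sd = 5e-4),
    indices = list(x_savi = 0.5, x_tsavi = 0.08, x_evi = 1,
                   gain = 2.5, c1 = 6, c2 = 7.5,
                   soil_slope = 1.2, soil_intercept = 0.04),
    screening = list(windows = c(8, 16), max_cloud_frac = 0.20),
    timeseries = list(period = 4, rolling_window = 4, adf_component = "residual"),
    calibration = list(x_lo = -0.3, x_hi = 1, step = 0.001),
    paths = list(scenes = NULL, lai = NULL, out_dir = NULL)
  )
  cfg <- utils::modifyList(defaults, list(...))
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level sections mirror
#' [pipeline_config()] (`simulate:`, `indices:`, `screening:`,
#' `timeseries:`, `calibration:`, `paths:`, `seed:`) and merges it over
#' the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

stop_rows <- function(bad, what, file) {
  if (any(bad)) {
    rows <- which(bad)
    stop(sprintf("%s: %s at data row(s) %s", file, what,
                 paste(utils::head(rows, 5), collapse = ", ")))
  }
}

#' Read and validate a reflectance scene table
#'
#' Reads `scenes.csv` (columns `date`, `blue`, `green`, `red`, `nir`,
#' optional `cloud_frac`), checking ISO-8601 dates and reflectance bounds
#' [0, 1]; malformed rows are reported with their row numbers.
#'
#' @param path CSV path.
#' @return Validated data frame with a `Date`-classed `date` column.
#' @export
read_scenes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "blue", "green", "red", "nir")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop(sprintf("%s: missing column(s) %s", path,
                                 paste(miss, collapse = ", ")))
  dates <- as.Date(d$date, format = "%Y-%m-%d")
  stop_rows(is.na(dates), "unparseable date", path)
  d$date <- dates
  for (bandname in c("blue", "green", "red", "nir")) {
    v <- suppressWarnings(as.numeric(d[[bandname]]))
    stop_rows(is.na(v) | v < 0 | v > 1,
              sprintf("reflectance '%s' missing or outside [0, 1]", bandname), path)
    d[[bandname]] <- v
  }
  d
}

#' Read and validate an LAI composite table
#'
#' Reads `lai.csv` (columns `date`, `lai`), checking dates and
#' non-negative LAI.
#'
#' @param path CSV path.
#' @return Validated data frame sorted by date.
#' @export
read_lai_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "lai") %in% names(d))) {
    stop(sprintf("%s: needs columns date, lai", path))
  }
  dates <- as.Date(d$date, format = "%Y-%m-%d")
  stop_rows(is.na(dates), "unparseable date", path)
  d$date <- dates
  v <- suppressWarnings(as.numeric(d$lai))
  stop_rows(is.na(v) | v < 0, "lai missing or negative", path)
  d$lai <- v
  d[order(d$date), , drop = FALSE]
}

#' Read field LAI site records
#'
#' Reads `field.csv` with columns `site`, `latitude`, `longitude`, `lai`,
#' `lai_is_range`, `date_start`, `date_end`, `biome` and optional
#' reflectance columns.  Latitude/longitude and dates may be empty (they
#' are screened later by [clean_field_records()]).
#'
#' @param path CSV path.
#' @return Data frame with `Date`-classed date columns.
#' @export
read_field_records <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "latitude", "longitude", "lai", "lai_is_range",
            "date_start", "date_end")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop(sprintf("%s: missing column(s) %s", path,
                                 paste(miss, collapse = ", ")))
  d$date_start <- as.Date(d$date_start, format = "%Y-%m-%d")
  d$date_end <- as.Date(d$date_end, format = "%Y-%m-%d")
  d$lai_is_range <- as.logical(d$lai_is_range)
  d
}

#' Write a stage table as CSV
#'
#' Plain UTF-8 CSV with a header row and ISO-8601 dates; the write/read
#' round trip preserves values.
#'
#' @param table Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: simulate (or load) scenes and LAI
#' composites; compute indices; screen scenes (cloud fraction and
#' vegetation mask) and temporally match LAI to each scene, merging
#' same-day records; quarterly-aggregate, gap-fill and decompose the LAI
#' series and test the chosen component for stationarity; and run the
#' exhaustive search for the optimal SAVI soil adjustment factor on the
#' matched records.  When `config$paths$out_dir` is set, stage tables
#' (`scenes.csv`, `lai.csv`, `matched.csv`, `decomposition.csv`,
#' `search.csv`) and a JSON `manifest.json` (settings, seed, per-stage
#' row counts, ADF summary, optimum) are written there.  The run is
#' deterministic for a fixed configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @return A list with elements `scenes`, `lai`, `matched`, `quarterly`,
#'   `decomposition`, `adf`, `search` and `manifest`, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  soil <- soil_line(config$indices$soil_slope, config$indices$soil_intercept)
  cfg <- vi_config(config$indices$x_savi, config$indices$x_tsavi,
                   config$indices$x_evi, config$indices$gain,
                   config$indices$c1, config$indices$c2, soil)

  if (isTRUE(config$simulate$enabled)) {
    sim <- config$simulate
    ds <- simulate_dataset(seed = config$seed, mean_lai = sim$mean_lai,
                           seasonal_amplitude = sim$seasonal_amplitude,
                           trend_per_year = sim$trend_per_year,
                           noise_sd = sim$noise_sd,
                           missing_prob = sim$missing_prob,
                           start_date = sim$start_date, end_date = sim$end_date,
                           scene_cadence_days = sim$scene_cadence_days,
                           lai_cadence_days = sim$lai_cadence_days,
                           band_noise_sd = sim$band_noise_sd)
    scenes <- ds$scenes; lai_tab <- ds$lai
  } else {
    scenes <- read_scenes(config$paths$scenes)
    lai_tab <- read_lai_table(config$paths$lai)
  }
  n_scenes_in <- nrow(scenes)

  # screening: cloud-cover filter, indices, scene-level vegetation mask
  if (!is.null(scenes$cloud_frac)) {
    scenes <- scenes[scenes$cloud_frac < config$screening$max_cloud_frac, ,
                     drop = FALSE]
  }
  n_after_cloud <- nrow(scenes)
  scenes <- add_indices(scenes, cfg)
  scenes <- scenes[vegetation_mask(scenes$ndvi, scenes$grvi), , drop = FALSE]
  n_after_veg <- nrow(scenes)

  # temporal matching of LAI composites
  matched_lai <- vapply(scenes$date, function(d) {
    match_lai(d, lai_tab, config$screening$windows)$lai
  }, numeric(1))
  matched <- scenes[!is.na(matched_lai), , drop = FALSE]
  matched$lai <- matched_lai[!is.na(matched_lai)]
  matched <- merge_same_day(matched)

  # time-series stage on the matched LAI record
  qs <- quarterly_mean(matched[, c("date", "lai")])
  qs <- fill_gaps(qs)
  dec <- decompose_multiplicative(qs, period = config$timeseries$period)
  comp <- config$timeseries$adf_component
  adf_series <- switch(comp,
                       residual = dec$residual[!is.na(dec$residual)],
                       observed = dec$observed,
                       stop(sprintf("unknown adf_component '%s'", comp)))
  adf <- adf_test(adf_series)

  # calibration stage
  cal <- config$calibration
  fit <- savi_search(matched, x_lo = cal$x_lo, x_hi = cal$x_hi, step = cal$step)

  settings <- unclass(config)
  settings$paths <- NULL  # keep the manifest reproducible across machines
  manifest <- list(
    seed = config$seed,
    settings = settings,
    rows = list(scenes_in = n_scenes_in, scenes_after_cloud = n_after_cloud,
                scenes_after_vegetation = n_after_veg,
                matched = nrow(matched), quarters = nrow(qs),
                search_grid = nrow(fit$table)),
    adf = list(statistic = adf$statistic, p_value = adf$p_value,
               lags_used = adf$lags_used, n_obs_used = adf$n_obs_used,
               critical_values = as.list(adf$critical_values)),
    optimum = list(x_opt = fit$x_opt, r2_signed = fit$opt$r2_signed,
                   p_value = fit$opt$p_value, n = fit$n)
  )

  out_dir <- config$paths$out_dir
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    if (isTRUE(config$simulate$enabled)) {
      write_table(ds$scenes, file.path(out_dir, "scenes.csv"))
      write_table(ds$lai, file.path(out_dir, "lai.csv"))
    }
    write_table(matched, file.path(out_dir, "matched.csv"))
    dec_tab <- data.frame(year = qs$year, quarter = qs$quarter,
                          observed = dec$observed, trend = dec$trend,
                          seasonal = dec$seasonal, residual = dec$residual)
    write_table(dec_tab, file.path(out_dir, "decomposition.csv"))
    write_table(search_report(fit), file.path(out_dir, "search.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(scenes = scenes, lai = lai_tab, matched = matched,
                 quarterly = qs, decomposition = dec, adf = adf,
                 search = fit, manifest = manifest))
}
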