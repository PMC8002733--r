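#' Vegetation pixel mask
#'
#' Classifies pixels as vegetation using the two-branch threshold rule:
#' a pixel is vegetation when `NDVI > 0.40`, or when
#' `0.36 <= NDVI <= 0.40` and `GRVI > 2.50`.
#'
#' @param ndvi_value,grvi_value Numeric vectors of per-pixel NDVI and GRVI.
#' @return Logical vector, `TRUE` for vegetation pixels.
#' @examples
#' vegetation_mask(c(0.5, 0.38, 0.38, 0.1), c(1, 2.6, 2.4, 10))
#' @export
vegetation_mask <- function(ndvi_value, grvi_value) {
  stopifnot(is.numeric(ndvi_value), is.numeric(grvi_value),
            all(is.finite(ndvi_value)), all(is.finite(grvi_value)))
  ndvi_value > 0.40 |
    (ndvi_value >= 0.36 & ndvi_value <= 0.40 & grvi_value > 2.50)
}

#' Aggregate a scene from screened pixels
#'
#' Applies the cloud mask and the vegetation mask to the pixels of one
#' scene, then averages.  Indices are computed *per pixel* and averaged
#' afterwards — the mean VI of the surviving pixels, not the VI of the
#' mean reflectance.
#'
#' @param pixels Data frame with columns `blue`, `green`, `red`, `nir` and
#'   optionally `cloud_flag` (logical; flagged pixels are removed).
#' @param cfg A [vi_config()].
#' @param date Optional scene date carried into the result.
#' @return A one-row data frame with `date` (if given), mean reflectance
#'   per band, mean `ndvi`/`savi`/`tsavi`/`evi`/`grvi`, and `n_pixels`,
#'   the number of pixels surviving both masks.
#' @section Scene rejection:
#' If no pixel survives both masks the scene is rejected: an error of
#' class `saviopt_scene_rejected` is signalled.
#' @export
aggregate_scene <- function(pixels, cfg = vi_config(), date = NULL) {
  stopifnot(is.data.frame(pixels))
  if (!is.null(pixels$cloud_flag)) {
    pixels <- pixels[!as.logical(pixels$cloud_flag), , drop = FALSE]
  }
  if (nrow(pixels) > 0) {
    idx <- add_indices(pixels[, c("blue", "green", "red", "nir")], cfg)
    keep <- vegetation_mask(idx$ndvi, idx$grvi)
    idx <- idx[keep, , drop = FALSE]
  } else {
    idx <- pixels
  }
  if (nrow(idx) == 0) {
    stop(errorCondition("scene rejected: no pixel survives cloud and vegetation masks",
                        class = c("saviopt_scene_rejected", "error", "condition")))
  }
  out <- as.data.frame(as.list(colMeans(idx)))
  out$n_pixels <- nrow(idx)
  if (!is.null(date)) out <- cbind(data.frame(date = as.Date(date)), out)
  out
}

#' Match an LAI record to a reflectance scene date
#'
#' Searches the LAI series within 8 days of the scene date; all composites
#' inside the window are averaged.  If none exists the window widens to
#' 16 days; if that also fails the scene is rejected (returned as an
#' `NA` match, a signalled outcome rather than an error).
#'
#' @param scene_date Scene acquisition date.
#' @param lai_series Data frame with columns `date`, `lai`, sorted by date.
#' @param windows Successive half-widths of the symmetric search windows,
#'   in days.
#' @return A list with `lai` (mean LAI of the matched window, `NA` on
#'   rejection), `window` (the half-width that matched, `NA` on rejection)
#'   and `n_used` (number of composites averaged).
#' @examples
#' s <- data.frame(date = as.Date("2020-01-01") + c(0, 12), lai = c(5, 6))
#' match_lai(as.Date("2020-01-03"), s)
#' @export
match_lai <- function(scene_date, lai_series, windows = c(8, 16)) {
  stopifnot(is.data.frame(lai_series), all(c("date", "lai") %in% names(lai_series)))
  scene_date <- as.Date(scene_date)
  delta <- abs(as.numeric(as.Date(lai_series$date) - scene_date))
  for (w in windows) {
    hit <- delta <= w
    if (any(hit)) {
      return(list(lai = mean(lai_series$lai[hit]), window = w,
                  n_used = sum(hit)))
    }
  }
  list(lai = NA_real_, window = NA_real_, n_used = 0L)
}

#' Merge records acquired on the same day
#'
#' When several scenes cover the study area on one calendar date, their
#' records are averaged into a single row per date.  All numeric columns
#' are averaged; the result is sorted by date.
#'
#' @param records Data frame with a `date` column and numeric fields.
#' @return Data frame with one row per distinct date.
#' @export
merge_same_day <- function(records) {
  stopifnot(is.data.frame(records), "date" %in% names(records))
  records$date <- as.Date(records$date)
  num <- names(records)[vapply(records, is.numeric, logical(1))]
  agg <- stats::aggregate(records[num], by = list(date = records$date), FUN = mean)
  agg[order(agg$date), c("date", num), drop = FALSE]
}

#' Clean field-measured LAI records
#'
#' Applies, in order, the screening rules for site-level field LAI
#' records (emulating the cleaning of a global field LAI compilation):
#' \enumerate{
#'   \item drop records with missing latitude, longitude or measurement
#'     dates;
#'   \item drop records whose LAI is a range rather than a single value;
#'   \item drop records whose measurement span exceeds one month
#'     (implemented as > 31 days for determinism);
#'   \item drop records with LAI below 4.0 (the dense-vegetation screen);
#'   \item drop records outside the sensor coverage window;
#'   \item drop *every* member of any group sharing (latitude, longitude,
#'     measurement dates) whose LAI values disagree — no one-to-one
#'     LAI/reflectance relation can be established for them; exact
#'     duplicates are collapsed to one row.
#' }
#' The operation is idempotent.
#'
#' @param records Data frame with columns `site`, `latitude`, `longitude`,
#'   `lai`, `lai_is_range` (logical), `date_start`, `date_end` and
#'   optionally `biome` and reflectance columns.
#' @param sensor_start,sensor_end Coverage window of the reference sensor;
#'   defaults span the Landsat-5 mission (1984-03-01 to 2013-06-05).
#' @return The surviving records, row order preserved.
#' @export
clean_field_records <- function(records,
                                sensor_start = as.Date("1984-03-01"),
                                sensor_end = as.Date("2013-06-05")) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) return(records)
  sensor_start <- as.Date(sensor_start); sensor_end <- as.Date(sensor_end)
  r <- records
  r$date_start <- as.Date(r$date_start); r$date_end <- as.Date(r$date_end)
  if (any(!is.na(r$latitude) & abs(r$latitude) > 90) ||
      any(!is.na(r$longitude) & abs(r$longitude) > 180)) {
    stop("latitude/longitude out of range")
  }
  # (1) nulls
  r <- r[!is.na(r$latitude) & !is.na(r$longitude) &
           !is.na(r$date_start) & !is.na(r$date_end), , drop = FALSE]
  # (2) range-valued LAI
  if (!is.null(r$lai_is_range)) {
    r <- r[!as.logical(r$lai_is_range) %in% TRUE, , drop = FALSE]
  }
  r <- r[!is.na(r$lai), , drop = FALSE]
  # (3) span over one month
  r <- r[as.numeric(r$date_end - r$date_start) <= 31, , drop = FALSE]
  # (4) dense-vegetation screen
  r <- r[r$lai >= 4.0, , drop = FALSE]
  # (5) sensor coverage window
  r <- r[r$date_start >= sensor_start & r$date_end <= sensor_end, , drop = FALSE]
  if (nrow(r) == 0) return(r)
  # (6) conflicting duplicates: same place and dates, different LAI
  key <- paste(r$latitude, r$longitude, r$date_start, r$date_end)
  n_lai <- tapply(r$lai, key, function(v) length(unique(v)))
  r <- r[n_lai[key] == 1L, , drop = FALSE]
  if (nrow(r) > 0) {
    key <- paste(r$latitude, r$longitude, r$date_start, r$date_end)
    r <- r[!duplicated(key), , drop = FALSE]
  }
  r
}
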