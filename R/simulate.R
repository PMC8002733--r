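#' Simulate a seasonal LAI time series
#'
#' Generates an LAI record emulating a 4-day satellite LAI composite over a
#' dense, seasonally cycling canopy: a sinusoidal annual cycle (365.25-day
#' period) around `mean_lai`, a linear trend, i.i.d. Gaussian noise, and
#' cloud-induced gaps in which entries are dropped independently with
#' probability `missing_prob`.  Values are clipped at zero.
#'
#' Random draws are consumed in a fixed order — first the `n` noise
#' deviates, then the `n` missingness uniforms — so a given seed yields
#' the same series regardless of which features are switched off.
#'
#' @param mean_lai Mean LAI level (default 5.5, a dense broadleaf canopy).
#' @param seasonal_amplitude Amplitude of the annual sinusoid.
#' @param trend_per_year Linear trend in LAI units per year.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param missing_prob Probability an entry is dropped (cloud gap).
#' @param start_date,end_date Series span (`Date` or ISO-8601 strings).
#' @param cadence_days Days between consecutive entries (default 4).
#' @param phase Phase of the sinusoid in radians.
#' @param seed Optional integer seed for reproducibility.
#' @return A data frame with columns `date` (Date) and `lai` (numeric).
#' @examples
#' head(simulate_lai_series(seed = 1))
#' @export
simulate_lai_series <- function(mean_lai = 5.5, seasonal_amplitude = 1,
                                trend_per_year = 0, noise_sd = 0.3,
                                missing_prob = 0.1,
                                start_date = "2013-04-16",
                                end_date = "2020-10-21",
                                cadence_days = 4, phase = 0, seed = NULL) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (end_date < start_date) stop("end_date before start_date")
  stopifnot(mean_lai > 0, noise_sd >= 0, missing_prob >= 0, missing_prob < 1,
            cadence_days >= 1)
  if (!is.null(seed)) set.seed(seed)
  dates <- seq(start_date, end_date, by = cadence_days)
  n <- length(dates)
  doy <- as.numeric(format(dates, "%j"))
  years <- as.numeric(dates - start_date) / 365.25
  noise <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else {
    stats::rnorm(n) * 0  # consume draws so the order contract holds
  }
  lai <- mean_lai + seasonal_amplitude * sin(2 * pi * doy / 365.25 + phase) +
    trend_per_year * years + noise
  lai <- pmax(lai, 0)
  keep <- stats::runif(n) >= missing_prob
  data.frame(date = dates[keep], lai = lai[keep])
}

#' Simulate reflectance scenes over a canopy LAI trajectory
#'
#' Produces one multiband scene per row of `lai_series` by running the
#' Beer--Lambert canopy model with a per-scene soil background drawn
#' uniformly from `params$soil_red_range`, additive Gaussian band noise
#' (clipped to [0, 1]), and a per-scene cloud fraction drawn uniformly
#' from `cloud_frac_range`.  Draw order per call: soil backgrounds, then
#' band noise (scene-major, band order blue/green/red/nir), then cloud
#' fractions.
#'
#' @param lai_series Data frame with columns `date` and `lai` (e.g. from
#'   [simulate_lai_series()]).
#' @param soil A [soil_line()].
#' @param params A [canopy_params()].
#' @param band_noise_sd Gaussian noise standard deviation added to every
#'   band (reflectance units).  The default 5e-4 is a scene-mean scale:
#'   each scene averages thousands of pixels, so per-pixel reflectance
#'   noise of ~1\% shrinks well below 0.001 in the mean.
#' @param cloud_frac_range Interval from which the per-scene cloud cover
#'   fraction is drawn.
#' @param seed Optional integer seed.
#' @return A data frame with columns `date`, `blue`, `green`, `red`,
#'   `nir`, `cloud_frac`.
#' @export
simulate_scenes <- function(lai_series, soil = soil_line(),
                            params = canopy_params(), band_noise_sd = 5e-4,
                            cloud_frac_range = c(0, 0.35), seed = NULL) {
  stopifnot(is.data.frame(lai_series), all(c("date", "lai") %in% names(lai_series)),
            band_noise_sd >= 0, length(cloud_frac_range) == 2L)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(lai_series)
  soil_red <- stats::runif(n, params$soil_red_range[1], params$soil_red_range[2])
  sc <- simulate_canopy(lai_series$lai, soil_red, soil, params)
  noise <- matrix(stats::rnorm(4L * n, 0, band_noise_sd), nrow = n)
  for (j in seq_along(sc)) {
    sc[[j]] <- pmin(pmax(sc[[j]] + noise[, j], 0), 1)
  }
  cloud <- stats::runif(n, cloud_frac_range[1], cloud_frac_range[2])
  cbind(data.frame(date = as.Date(lai_series$date)), sc,
        data.frame(cloud_frac = cloud))
}

#' Planted-optimum reflectance dataset
#'
#' Constructs (reflectance, LAI) pairs for which SAVI evaluated at a chosen
#' soil adjustment factor `x_star` is *exactly* linear in LAI with slope
#' `slope_c` and intercept `intercept_d` — a ground-truth dataset on which
#' the exhaustive search must recover `x_star`.  The construction fixes the
#' band sum `S = nir + red` per sample and sets
#' `nir - red = (c * lai + d) * (S + x_star) / (1 + x_star)`, so that
#' `SAVI(x_star) = (nir - red) * (1 + x_star) / (S + x_star) = c * lai + d`
#' identically.
#'
#' The band sum must vary across samples for the optimum to be
#' identifiable: with a constant `S`, SAVI at *every* X is a fixed multiple
#' of `nir - red` and hence perfectly linear in LAI, so the search surface
#' is flat at R-squared 1.  `total_s` is therefore an interval from which
#' per-sample sums are drawn uniformly (a scalar is accepted but yields
#' that degenerate flat surface).
#'
#' @param x_star The soil adjustment factor at which SAVI is linear in LAI.
#' @param n Number of samples.
#' @param lai_range Interval from which LAI is drawn uniformly.
#' @param slope_c,intercept_d Planted regression slope and intercept
#'   (LAI units per SAVI unit and SAVI units respectively, inverted below).
#' @param total_s Interval (or scalar) of per-sample band sums `nir + red`.
#' @param band_noise_sd Gaussian noise added to red and NIR after the
#'   construction (0 = noiseless identity).
#' @param seed Optional integer seed.
#' @return A data frame with columns `lai`, `blue`, `green`, `red`, `nir`.
#' @examples
#' d <- plant_optimum_dataset(x_star = -0.148, n = 50, seed = 1)
#' max(abs(savi(d, x = -0.148) - 0.08 * d$lai))  # ~1e-16
#' @export
plant_optimum_dataset <- function(x_star, n = 200, lai_range = c(4, 7),
                                  slope_c = 0.08, intercept_d = 0,
                                  total_s = c(0.35, 0.9),
                                  band_noise_sd = 0, seed = NULL) {
  stopifnot(is.numeric(x_star), length(x_star) == 1L, n >= 2,
            length(lai_range) == 2L, lai_range[1] <= lai_range[2],
            band_noise_sd >= 0)
  if (length(total_s) == 1L) total_s <- c(total_s, total_s)
  if (x_star <= -min(total_s) || x_star <= -1) {
    stop("x_star must keep both 1 + x_star and total_s + x_star positive")
  }
  if (!is.null(seed)) set.seed(seed)
  lai <- stats::runif(n, lai_range[1], lai_range[2])
  s <- stats::runif(n, total_s[1], total_s[2])
  diff <- (slope_c * lai + intercept_d) * (s + x_star) / (1 + x_star)
  red <- (s - diff) / 2
  nir <- (s + diff) / 2
  if (band_noise_sd > 0) {
    red <- red + stats::rnorm(n, 0, band_noise_sd)
    nir <- nir + stats::rnorm(n, 0, band_noise_sd)
  }
  if (any(red <= 0) || any(red >= 1) || any(nir <= 0) || any(nir >= 1)) {
    stop("infeasible parameters: generated bands left (0, 1)")
  }
  data.frame(lai = lai, blue = 0.5 * red, green = 0.6 * red,
             red = red, nir = nir)
}

#' Simulate a matched scene/LAI study dataset
#'
#' Convenience generator for end-to-end runs: an LAI "truth" trajectory, a
#' gappy LAI record derived from it (emulating a 4-day LAI composite), and
#' reflectance scenes on an independent acquisition cadence.  Seeds for the
#' three stages are derived deterministically from `seed`.
#'
#' @param seed Integer seed driving all three generators.
#' @param mean_lai,seasonal_amplitude,trend_per_year,noise_sd,missing_prob
#'   Passed to [simulate_lai_series()].
#' @param start_date,end_date Study span.
#' @param scene_cadence_days Days between reflectance acquisitions
#'   (default 8, a Landsat-like revisit).
#' @param lai_cadence_days Days between LAI composites (default 4).
#' @param band_noise_sd,cloud_frac_range Passed to [simulate_scenes()].
#' @return A list with data frames `scenes` (date, bands, cloud_frac),
#'   `lai` (date, lai) and `truth` (the scene-date LAI driving the
#'   reflectance).
#' @export
simulate_dataset <- function(seed = 1, mean_lai = 5.5, seasonal_amplitude = 1,
                             trend_per_year = 0, noise_sd = 0.3,
                             missing_prob = 0.1,
                             start_date = "2013-04-16", end_date = "2020-10-21",
                             scene_cadence_days = 8, lai_cadence_days = 4,
                             band_noise_sd = 5e-4,
                             cloud_frac_range = c(0, 0.35)) {
  truth <- simulate_lai_series(mean_lai, seasonal_amplitude, trend_per_year,
                               noise_sd = 0, missing_prob = 0,
                               start_date = start_date, end_date = end_date,
                               cadence_days = scene_cadence_days,
                               seed = seed)
  lai <- simulate_lai_series(mean_lai, seasonal_amplitude, trend_per_year,
                             noise_sd = noise_sd, missing_prob = missing_prob,
                             start_date = start_date, end_date = end_date,
                             cadence_days = lai_cadence_days,
                             seed = seed + 1000L)
  scenes <- simulate_scenes(truth, band_noise_sd = band_noise_sd,
                            cloud_frac_range = cloud_frac_range,
                            seed = seed + 2000L)
  list(scenes = scenes, lai = lai, truth = truth)
}
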