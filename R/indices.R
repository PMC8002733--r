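#' @keywords internal
band <- function(sample, name) {
  v <- sample[[name]]
  if (is.null(v)) stop(sprintf("sample has no '%s' band", name))
  as.numeric(v)
}

# Denominators inside this guard are treated as degenerate and raised,
# never returned as infinities.
.den_tol <- 1e-12

check_den <- function(den, what) {
  if (any(abs(den) <= .den_tol)) {
    stop(sprintf("degenerate input: %s denominator is zero", what))
  }
  den
}

#' Normalized difference vegetation index
#'
#' `NDVI = (N - R) / (N + R)` with `N` and `R` the NIR and red surface
#' reflectance.  Bounded in [-1, 1] for nonnegative bands and invariant to
#' a common rescaling of both bands.
#'
#' @param sample A data frame or named list with (at least) numeric
#'   elements `nir` and `red`; all index functions are vectorised over its
#'   rows.
#' @return Numeric vector of index values.
#' @examples
#' ndvi(list(nir = 0.3, red = 0.1))  # 0.5
#' @export
ndvi <- function(sample) {
  n <- band(sample, "nir"); r <- band(sample, "red")
  (n - r) / check_den(n + r, "NDVI")
}

#' Soil-adjusted vegetation index
#'
#' `SAVI = (N - R) * (1 + X) / (N + R + X)` with soil adjustment factor
#' `X`.  `X = 0.5` is the classical recommendation; `X = 0` reduces SAVI
#' to NDVI exactly.  In dense canopies the optimal `X` can be negative —
#' calibrating it is what [savi_search()] does.
#'
#' @inheritParams ndvi
#' @param x Soil adjustment factor (dimensionless).
#' @return Numeric vector of index values.
#' @examples
#' savi(list(nir = 0.4, red = 0.1), x = 0.5)  # 0.45
#' @export
savi <- function(sample, x = 0.5) {
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x))
  n <- band(sample, "nir"); r <- band(sample, "red")
  (n - r) * (1 + x) / check_den(n + r + x, "SAVI")
}

#' Transformed soil-adjusted vegetation index
#'
#' `TSAVI = a * (N - a * R - b) / (a * N + R - a * b + X * (1 + a^2))`
#' where `(a, b)` are the soil line slope and intercept.  Bare-soil points
#' (`N = a * R + b`) score exactly zero for any `X`.
#'
#' @inheritParams ndvi
#' @param soil A [soil_line()].
#' @param x Soil adjustment factor (default 0.08, the original
#'   recommendation).
#' @return Numeric vector of index values.
#' @export
tsavi <- function(sample, soil = soil_line(), x = 0.08) {
  stopifnot(inherits(soil, "soil_line"), is.numeric(x), length(x) == 1L)
  a <- soil$slope; b <- soil$intercept
  n <- band(sample, "nir"); r <- band(sample, "red")
  a * (n - a * r - b) /
    check_den(a * n + r - a * b + x * (1 + a^2), "TSAVI")
}

#' Enhanced vegetation index
#'
#' `EVI = G * (N - R) / (N + C1 * R - C2 * B + X)` with gain `G`, aerosol
#' resistance coefficients `C1` (red) and `C2` (blue) and soil adjustment
#' factor `X`.  Computed on surface reflectance as-is; the aerosol term
#' enters only through the printed constants.
#'
#' @inheritParams ndvi
#' @param cfg A [vi_config()] supplying `G`, `C1`, `C2` and `X_EVI`.
#' @return Numeric vector of index values.
#' @examples
#' evi(list(nir = 0.4, red = 0.1, blue = 0.05))  # 0.75/1.625
#' @export
evi <- function(sample, cfg = vi_config()) {
  stopifnot(inherits(cfg, "vi_config"))
  n <- band(sample, "nir"); r <- band(sample, "red"); b <- band(sample, "blue")
  cfg$gain * (n - r) /
    check_den(n + cfg$c1 * r - cfg$c2 * b + cfg$x_evi, "EVI")
}

#' Green ratio vegetation index
#'
#' The simple ratio `NIR / green`, used together with NDVI to mask
#' vegetation pixels.
#'
#' @inheritParams ndvi
#' @return Numeric vector of index values.
#' @export
grvi <- function(sample) {
  n <- band(sample, "nir"); g <- band(sample, "green")
  if (any(g <= .den_tol)) stop("degenerate input: green band is zero")
  n / g
}

#' Append vegetation index columns to a reflectance table
#'
#' Computes all five indices per row of `sample` and returns the table
#' with columns `ndvi`, `savi`, `tsavi`, `evi`, `grvi` appended, using the
#' factors in `cfg`.
#'
#' @param sample Data frame with `blue`, `green`, `red`, `nir` columns.
#' @param cfg A [vi_config()].
#' @return `sample` with the five index columns added.
#' @export
add_indices <- function(sample, cfg = vi_config()) {
  sample$ndvi <- ndvi(sample)
  sample$savi <- savi(sample, cfg$x_savi)
  sample$tsavi <- tsavi(sample, cfg$soil, cfg$x_tsavi)
  sample$evi <- evi(sample, cfg)
  sample$grvi <- grvi(sample)
  sample
}
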