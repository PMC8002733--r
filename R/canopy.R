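#' Beer--Lambert canopy parameters
#'
#' Parameters of the minimal mechanistic canopy reflectance model used by
#' [simulate_canopy()]: per-band extinction coefficients `k` (per unit LAI)
#' and asymptotic dense-canopy reflectances `rho_inf`, plus the interval of
#' admissible bare-soil red reflectance.  Per band, canopy reflectance is a
#' soil/vegetation mixture
#' `rho(lai) = rho_soil * exp(-k * lai) + rho_inf * (1 - exp(-k * lai))`,
#' which reproduces the three geometric facts the analysis leans on: a soil
#' line at `lai = 0`, straight vegetation isolines in the red--NIR plane
#' whose slope is `a * exp((k_red - k_nir) * lai)`, and saturation of
#' red-based indices at high LAI.
#'
#' Defaults (`k`: blue 0.6, green 0.5, red 0.9, nir 0.4; `rho_inf`: blue
#' 0.05, green 0.12, red 0.07, nir 0.50; soil red in [0.05, 0.30]) give
#' NDVI around 0.74 at LAI 5--6, inside the 0.7--0.9 range reported for
#' dense broadleaf canopies, and place the convergence of high-LAI
#' vegetation isolines near red 0.07 in the first quadrant — the
#' geometry under which the optimal SAVI soil adjustment factor is
#' negative.  Red must be absorbed more strongly than blue
#' (`k_red > k_blue`), the property that makes EVI's blue band retain
#' sensitivity after the red band saturates.
#'
#' @param k Named numeric vector of extinction coefficients for
#'   `blue`, `green`, `red`, `nir`; all positive.
#' @param rho_inf Named numeric vector of asymptotic reflectances for the
#'   same four bands; each in (0, 1).
#' @param soil_red_range Length-2 interval of admissible bare-soil red
#'   reflectance.
#' @return An object of class `canopy_params`.
#' @export
canopy_params <- function(k = c(blue = 0.6, green = 0.5, red = 0.9, nir = 0.4),
                          rho_inf = c(blue = 0.05, green = 0.12,
                                      red = 0.07, nir = 0.50),
                          soil_red_range = c(0.05, 0.30)) {
  bands <- c("blue", "green", "red", "nir")
  if (!all(bands %in% names(k)) || !all(bands %in% names(rho_inf))) {
    stop("k and rho_inf must be named with blue, green, red, nir")
  }
  k <- k[bands]; rho_inf <- rho_inf[bands]
  if (any(!is.finite(k)) || any(k <= 0)) stop("all extinction coefficients must be positive")
  if (any(!is.finite(rho_inf)) || any(rho_inf <= 0) || any(rho_inf >= 1)) {
    stop("asymptotic reflectances must lie in (0, 1)")
  }
  if (k[["red"]] <= k[["blue"]]) {
    stop("k_red must exceed k_blue (red is absorbed more strongly than blue)")
  }
  stopifnot(length(soil_red_range) == 2L, soil_red_range[1] < soil_red_range[2],
            soil_red_range[1] >= 0, soil_red_range[2] <= 1)
  structure(list(k = k, rho_inf = rho_inf, soil_red_range = soil_red_range),
            class = "canopy_params")
}

# Bare-soil spectrum for a given red reflectance.  Red and NIR sit exactly on
# the soil line; blue and green are fixed fractions of red (bright-soil
# spectral slope), a modeling choice documented in the methods vignette.
soil_spectrum <- function(soil_red, soil) {
  data.frame(blue = 0.90 * soil_red,
             green = 0.95 * soil_red,
             red = soil_red,
             nir = soil$slope * soil_red + soil$intercept)
}

#' Simulate canopy reflectance over a soil background
#'
#' Computes blue/green/red/NIR surface reflectance of a canopy of leaf area
#' index `lai` over bare soil of red reflectance `soil_red`, using the
#' Beer--Lambert soil/vegetation mixture described in [canopy_params()].
#' At `lai = 0` the sample is exactly the bare-soil spectrum (red/NIR on
#' the soil line); as `lai` grows each band converges to its asymptotic
#' dense-canopy reflectance.
#'
#' @param lai Leaf area index, non-negative; vectorised.
#' @param soil_red Bare-soil red reflectance, inside
#'   `params$soil_red_range`; recycled against `lai`.
#' @param soil A [soil_line()].
#' @param params A [canopy_params()].
#' @return A data frame with columns `blue`, `green`, `red`, `nir`, one row
#'   per (lai, soil_red) pair; every value in [0, 1].
#' @examples
#' simulate_canopy(c(0, 1, 5), soil_red = 0.2)
#' @export
simulate_canopy <- function(lai, soil_red, soil = soil_line(),
                            params = canopy_params()) {
  stopifnot(is.numeric(lai), is.numeric(soil_red))
  if (any(!is.finite(lai)) || any(lai < 0)) stop("lai must be finite and >= 0")
  rng <- params$soil_red_range
  if (any(soil_red < rng[1] - 1e-12) || any(soil_red > rng[2] + 1e-12)) {
    stop(sprintf("soil_red outside admissible range [%g, %g]", rng[1], rng[2]))
  }
  n <- max(length(lai), length(soil_red))
  lai <- rep_len(lai, n); soil_red <- rep_len(soil_red, n)
  sp <- soil_spectrum(soil_red, soil)
  if (any(sp$nir > 1)) stop("soil line gives NIR reflectance above 1")
  out <- sp
  for (band in c("blue", "green", "red", "nir")) {
    w <- exp(-params$k[[band]] * lai)
    out[[band]] <- sp[[band]] * w + params$rho_inf[[band]] * (1 - w)
  }
  if (any(unlist(out) < 0) || any(unlist(out) > 1)) {
    stop("simulated reflectance left [0, 1]; invalid parameterization")
  }
  out
}

#' Vegetation isoline geometry in the red--NIR plane
#'
#' A vegetation isoline is the locus of (red, NIR) canopy reflectance at
#' fixed LAI as the soil background brightness varies.  Under the
#' Beer--Lambert mixture the isoline is a straight line with slope
#' `a * exp((k_red - k_nir) * lai)` (closed form).  This helper returns
#' that slope and intercept together with the isoline's intersection with
#' the soil line and the quadrant the intersection falls in.  When the
#' isoline intercept is below the soil line intercept the intersection
#' lies in the first quadrant — the regime in which a negative SAVI soil
#' adjustment factor is optimal; when above, in the second or third.
#'
#' @param lai Leaf area index (scalar, >= 0).
#' @param soil A [soil_line()].
#' @param params A [canopy_params()].
#' @param tol Slopes closer than this are treated as parallel.
#' @return An object of class `isoline_geometry`: list with `slope`,
#'   `intercept`, `intersection` (named c(red, nir), NA when parallel),
#'   `quadrant` (`"first"`, `"second"`, `"third"`, `"fourth"` or NA) and
#'   `parallel` (TRUE when no unique intersection exists, e.g. `lai = 0`
#'   where the isoline coincides with the soil line).
#' @export
isoline_geometry <- function(lai, soil = soil_line(), params = canopy_params(),
                             tol = 1e-10) {
  stopifnot(is.numeric(lai), length(lai) == 1L, is.finite(lai), lai >= 0)
  a <- soil$slope; b <- soil$intercept
  kr <- params$k[["red"]]; kn <- params$k[["nir"]]
  rr <- params$rho_inf[["red"]]; rn <- params$rho_inf[["nir"]]
  slope <- a * exp((kr - kn) * lai)
  # N = slope * R + intercept, from eliminating soil_red between the two bands
  intercept <- b * exp(-kn * lai) + rn * (1 - exp(-kn * lai)) -
    slope * rr * (1 - exp(-kr * lai))
  if (abs(slope - a) < tol) {
    return(structure(list(slope = slope, intercept = intercept,
                          intersection = c(red = NA_real_, nir = NA_real_),
                          quadrant = NA_character_, parallel = TRUE),
                     class = "isoline_geometry"))
  }
  red_star <- (intercept - b) / (a - slope)
  nir_star <- a * red_star + b
  quadrant <- if (red_star >= 0 && nir_star >= 0) "first"
  else if (red_star < 0 && nir_star >= 0) "second"
  else if (red_star < 0 && nir_star < 0) "third"
  else "fourth"
  structure(list(slope = slope, intercept = intercept,
                 intersection = c(red = red_star, nir = nir_star),
                 quadrant = quadrant, parallel = FALSE),
            class = "isoline_geometry")
}

#' @export
print.isoline_geometry <- function(x, ...) {
  cat(sprintf("Vegetation isoline: NIR = %.4g * red + %.4g\n",
              x$slope, x$intercept))
  if (x$parallel) {
    cat("  parallel/coincident with the soil line: no unique intersection\n")
  } else {
    cat(sprintf("  intersects soil line at (%.4g, %.4g) [%s quadrant]\n",
                x$intersection[["red"]], x$intersection[["nir"]], x$quadrant))
  }
  invisible(x)
}
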