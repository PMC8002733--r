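#' Soil line in the red--NIR reflectance plane
#'
#' Bare-soil reflectance points cluster on a near-linear locus in the
#' red--NIR plane, `nir = a * red + b`.  The defaults are the widely used
#' global soil line parameters `a = 1.2`, `b = 0.04`, which TSAVI and the
#' isoline geometry helpers take as reference.
#'
#' @param slope Soil line slope `a` (dimensionless, must be positive).
#' @param intercept Soil line intercept `b` (reflectance units).
#' @return An object of class `soil_line`: a list with elements `slope`
#'   and `intercept`.
#' @examples
#' sl <- soil_line()
#' sl$slope * 0.1 + sl$intercept  # NIR of a bare-soil point with red = 0.1
#' @export
soil_line <- function(slope = 1.2, intercept = 0.04) {
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope),
            is.numeric(intercept), length(intercept) == 1L, is.finite(intercept))
  if (slope <= 0) {
    stop("soil line slope must be positive")
  }
  structure(list(slope = slope, intercept = intercept), class = "soil_line")
}

#' @export
print.soil_line <- function(x, ...) {
  cat(sprintf("Soil line: NIR = %.4g * red + %.4g\n", x$slope, x$intercept))
  invisible(x)
}

#' Vegetation index configuration
#'
#' Bundles the constants of the SAVI-family indices: the soil adjustment
#' factors of SAVI, TSAVI and EVI, the EVI gain and aerosol-resistance
#' coefficients, and the soil line used by TSAVI.  Defaults are the values
#' recommended by the indices' original formulations (X_SAVI = 0.5,
#' X_TSAVI = 0.08, X_EVI = 1, G = 2.5, C1 = 6, C2 = 7.5; soil line
#' a = 1.2, b = 0.04).  No atmospheric correction is applied anywhere:
#' indices are computed on surface reflectance as given, so the EVI
#' aerosol term acts only through the printed constants.
#'
#' @param x_savi Soil adjustment factor of SAVI.
#' @param x_tsavi Soil adjustment factor of TSAVI.
#' @param x_evi Soil adjustment factor of EVI.
#' @param gain EVI gain factor G.
#' @param c1,c2 EVI aerosol resistance coefficients (red and blue band).
#' @param soil A [soil_line()] object used by TSAVI.
#' @return An object of class `vi_config`.
#' @export
vi_config <- function(x_savi = 0.5, x_tsavi = 0.08, x_evi = 1,
                      gain = 2.5, c1 = 6, c2 = 7.5, soil = soil_line()) {
  stopifnot(inherits(soil, "soil_line"))
  num1 <- function(z) is.numeric(z) && length(z) == 1L && is.finite(z)
  if (!all(vapply(list(x_savi, x_tsavi, x_evi, gain, c1, c2), num1, logical(1)))) {
    stop("all vi_config constants must be finite scalars")
  }
  structure(list(x_savi = x_savi, x_tsavi = x_tsavi, x_evi = x_evi,
                 gain = gain, c1 = c1, c2 = c2, soil = soil),
            class = "vi_config")
}

#' @export
print.vi_config <- function(x, ...) {
  cat("Vegetation index configuration\n")
  cat(sprintf("  X_SAVI = %g, X_TSAVI = %g, X_EVI = %g\n",
              x$x_savi, x$x_tsavi, x$x_evi))
  cat(sprintf("  EVI gain G = %g, C1 = %g, C2 = %g\n", x$gain, x$c1, x$c2))
  cat(sprintf("  soil line: a = %g, b = %g\n", x$soil$slope, x$soil$intercept))
  invisible(x)
}
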