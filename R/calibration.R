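# Closed-form OLS of y on each column of V, vectorised over columns.
# Returns slope, intercept, signed R-squared (sign(slope) * r^2), and the
# two-sided Wald-t p-value for slope = 0 with n - 2 df.
ols_columns <- function(V, y) {
  n <- length(y)
  my <- mean(y)
  mx <- colMeans(V)
  Vc <- sweep(V, 2L, mx)
  yc <- y - my
  sxx <- colSums(Vc^2)
  sxy <- colSums(Vc * yc)
  syy <- sum(yc^2)
  slope <- sxy / sxx
  intercept <- my - slope * mx
  r2 <- sxy^2 / (sxx * syy)
  rss <- syy - slope * sxy
  se <- sqrt(pmax(rss, 0) / ((n - 2) * sxx))
  tval <- slope / se
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  data.frame(slope = slope, intercept = intercept,
             r2_signed = sign(slope) * r2, p_value = p)
}

#' Linear LAI--VI regression with signed R-squared
#'
#' Ordinary least squares fit of `lai = c * vi + d`.  The reported
#' goodness of fit is the *signed* R-squared, `sign(c) * r^2` (squared
#' Pearson correlation carrying the slope's sign), so that a VI
#' negatively associated with LAI scores negatively — the convention
#' under which saturation-driven sign flips remain visible.  The p-value
#' is the two-sided Wald t-test of `c = 0` with `n - 2` degrees of
#' freedom.
#'
#' @param vi Numeric vector of vegetation index values (the regressor).
#' @param lai Numeric vector of LAI values, same length (the response).
#' @return An object of class `vi_regression`: list with `slope`,
#'   `intercept`, `r2_signed`, `p_value`, `n`.
#' @examples
#' fit_linear(1:10, 2 * (1:10) + 3)
#' @export
fit_linear <- function(vi, lai) {
  vi <- as.numeric(vi); lai <- as.numeric(lai)
  if (length(vi) != length(lai)) stop("vi and lai must have equal length")
  if (length(vi) < 3) stop("need at least 3 observations")
  if (anyNA(vi) || anyNA(lai)) stop("missing values in vi or lai")
  if (stats::sd(vi) == 0) stop("constant vi: slope inference undefined")
  row <- ols_columns(matrix(vi, ncol = 1), lai)
  structure(list(slope = row$slope, intercept = row$intercept,
                 r2_signed = row$r2_signed, p_value = row$p_value,
                 n = length(vi)),
            class = "vi_regression")
}

#' @export
print.vi_regression <- function(x, ...) {
  cat(sprintf("LAI = %.4f * VI + %.4f   (n = %d)\n", x$slope, x$intercept, x$n))
  cat(sprintf("  signed R-squared = %.4f, two-sided P = %.4g\n",
              x$r2_signed, x$p_value))
  invisible(x)
}

#' Exhaustive search for the optimal SAVI soil adjustment factor
#'
#' The package's core estimator.  For every X on the grid
#' `seq(x_lo, x_hi, by = step)` it computes `SAVI(X)` from the red/NIR
#' reflectance, regresses LAI on it ([fit_linear()]) and records slope,
#' intercept, signed R-squared and P.  The optimum `x_opt` maximises the
#' signed R-squared; ties are broken toward smaller `|X|`, then smaller
#' `X`.  Grid points at which any sample's SAVI denominator
#' `nir + red + X` vanishes are skipped with a warning.
#'
#' The default grid is X in [-0.3, 1] at steps of 0.001 (1301 points),
#' deliberately extending below zero: in dense canopies, where vegetation
#' isolines meet the soil line in the first quadrant of the red--NIR
#' plane, the optimum is negative.
#'
#' @param data Optional data frame with columns `red`, `nir`, `lai`
#'   (e.g. a matched scene/LAI table or [plant_optimum_dataset()]
#'   output).  Alternatively pass the three vectors directly.
#' @param red,nir Reflectance vectors (ignored when `data` is given).
#' @param lai LAI vector (ignored when `data` is given).
#' @param x_lo,x_hi,step Grid bounds and step for X.
#' @return An object of class `savi_search`: list with `table` (one row
#'   per evaluated X: `x`, `slope`, `intercept`, `r2_signed`, `p_value`),
#'   `x_opt`, `opt` (the optimal row), `n`, the input vectors and the
#'   call.  Methods: `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `plot`.
#' @examples
#' d <- plant_optimum_dataset(x_star = -0.148, n = 100, seed = 7)
#' fit <- savi_search(d)
#' fit$x_opt
#' @export
savi_search <- function(data = NULL, red = NULL, nir = NULL, lai = NULL,
                        x_lo = -0.3, x_hi = 1, step = 0.001) {
  cl <- match.call()
  if (!is.null(data)) {
    stopifnot(is.data.frame(data), all(c("red", "nir", "lai") %in% names(data)))
    red <- data$red; nir <- data$nir; lai <- data$lai
  }
  red <- as.numeric(red); nir <- as.numeric(nir); lai <- as.numeric(lai)
  stopifnot(length(red) == length(nir), length(red) == length(lai))
  if (length(red) < 3) stop("need at least 3 matched observations")
  if (!(step > 0)) stop("step must be positive")
  if (x_hi < x_lo) stop("x_hi must be >= x_lo")
  x_grid <- seq(x_lo, x_hi, by = step)

  s <- nir + red
  diffv <- nir - red
  den <- outer(s, x_grid, `+`)          # n x m denominators
  bad <- colSums(abs(den) <= .den_tol) > 0
  if (any(bad)) {
    warning(sprintf("skipping %d grid point(s) with zero SAVI denominator", sum(bad)))
  }
  V <- diffv * sweep(1 / den[, !bad, drop = FALSE], 2L, 1 + x_grid[!bad], `*`)
  tab <- ols_columns(V, lai)
  tab <- cbind(data.frame(x = x_grid[!bad]), tab)
  rownames(tab) <- NULL

  best <- max(tab$r2_signed)
  cand <- which(tab$r2_signed >= best - 1e-15)
  cand <- cand[order(abs(tab$x[cand]), tab$x[cand])]
  iopt <- cand[1]

  structure(list(table = tab, x_opt = tab$x[iopt], opt = tab[iopt, ],
                 n = length(lai), red = red, nir = nir, lai = lai,
                 x_lo = x_lo, x_hi = x_hi, step = step, call = cl),
            class = "savi_search")
}

#' @export
print.savi_search <- function(x, ...) {
  cat("Exhaustive SAVI soil-adjustment-factor search\n")
  cat(sprintf("  grid: [%g, %g] by %g (%d points), n = %d\n",
              x$x_lo, x$x_hi, x$step, nrow(x$table), x$n))
  cat(sprintf("  x_opt = %.3f  (signed R-squared %.4f, P %.4g)\n",
              x$x_opt, x$opt$r2_signed, x$opt$p_value))
  invisible(x)
}

#' @export
summary.savi_search <- function(object, ...) {
  structure(list(search = object,
                 at_zero = object$table[which.min(abs(object$table$x)), ],
                 at_half = object$table[which.min(abs(object$table$x - 0.5)), ]),
            class = "summary.savi_search")
}

#' @export
print.summary.savi_search <- function(x, ...) {
  print(x$search)
  o <- x$search$opt
  cat(sprintf("  regression at optimum: LAI = %.4f * SAVI + %.4f\n",
              o$slope, o$intercept))
  cat(sprintf("  reference: X = %g gives R2s = %.4f; X = %g (classical) gives R2s = %.4f\n",
              x$at_zero$x, x$at_zero$r2_signed, x$at_half$x, x$at_half$r2_signed))
  invisible(x)
}

#' @export
coef.savi_search <- function(object, ...) {
  c(x_opt = object$x_opt, slope = object$opt$slope,
    intercept = object$opt$intercept)
}

#' Predict LAI from reflectance at the calibrated factor
#'
#' Applies the regression fitted at `x_opt`: computes `SAVI(x_opt)` from
#' `newdata`'s `red` and `nir` columns and returns
#' `slope * SAVI + intercept`.
#'
#' @param object A [savi_search()] fit.
#' @param newdata Data frame with `red` and `nir` columns; defaults to
#'   the training data.
#' @param ... Unused.
#' @return Numeric vector of predicted LAI.
#' @export
predict.savi_search <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    v <- savi(list(red = object$red, nir = object$nir), object$x_opt)
  } else {
    v <- savi(newdata, object$x_opt)
  }
  object$opt$slope * v + object$opt$intercept
}

#' @export
fitted.savi_search <- function(object, ...) predict(object)

#' @export
residuals.savi_search <- function(object, ...) object$lai - fitted(object)

#' Plot the search curves
#'
#' Draws signed R-squared, slope, and P against the soil adjustment
#' factor X, marking the optimum — the tabular rendering of the classic
#' calibration figure.
#'
#' @param x A [savi_search()] fit.
#' @param ... Passed to the R-squared panel's `plot`.
#' @export
plot.savi_search <- function(x, ...) {
  tab <- x$table
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(tab$x, tab$r2_signed, type = "l", xlab = "X (soil adjustment factor)",
                 ylab = "signed R-squared", ...)
  graphics::abline(v = x$x_opt, lty = 2)
  graphics::plot(tab$x, tab$slope, type = "l", xlab = "X", ylab = "slope")
  graphics::abline(h = 0, v = x$x_opt, lty = 2)
  graphics::plot(tab$x, tab$p_value, type = "l", xlab = "X", ylab = "P")
  graphics::abline(v = x$x_opt, lty = 2)
  invisible(x)
}

#' Tabular report of an exhaustive search
#'
#' One row per evaluated grid point with the regression summaries and a
#' logical `is_optimal` flag on the argmax row.
#'
#' @param result A [savi_search()] fit.
#' @return Data frame with columns `x`, `slope`, `intercept`,
#'   `r2_signed`, `p_value`, `is_optimal` (exactly one `TRUE`).
#' @export
search_report <- function(result) {
  stopifnot(inherits(result, "savi_search"))
  tab <- result$table
  tab$is_optimal <- tab$x == result$x_opt
  tab
}
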