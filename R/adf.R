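# MacKinnon response-surface coefficients, constant-only (no trend) case,
# single unit root.  Critical values use the 2010 response surface
# cv = b0 + b1/n + b2/n^2 + b3/n^3; approximate asymptotic p-values use the
# 1994 normal-quantile polynomials with their published validity range.
.mackinnon_cv_c <- list(
  "1%"  = c(-3.43035, -6.5393, -16.786, -79.433),
  "5%"  = c(-2.86154, -2.8903, -4.234, -40.040),
  "10%" = c(-2.56677, -1.5384, -2.809, 0)
)
.mackinnon_p_c <- list(
  tau_star = -1.61, tau_min = -18.83, tau_max = 2.74,
  small = c(2.1659, 1.4412, 0.038269),            # used for tau <= tau_star
  large = c(1.7339, 0.93202, -0.12745, -0.010368) # used for tau >  tau_star
)

#' MacKinnon critical values for the constant-only ADF test
#'
#' Finite-sample critical values from the MacKinnon response surface
#' `cv = b_inf + b1/n + b2/n^2 + b3/n^3` for the augmented Dickey--Fuller
#' t-statistic with a constant and no trend (single unit root).
#'
#' @param n_obs Number of observations used by the ADF regression
#'   (must be at least 10).
#' @return Named numeric vector of critical values at the 1%, 5% and 10%
#'   levels, strictly increasing from 1% to 10%.
#' @examples
#' mackinnon_critical_values(26)  # -3.711, -2.981, -2.630
#' @export
mackinnon_critical_values <- function(n_obs) {
  stopifnot(is.numeric(n_obs), length(n_obs) == 1L, n_obs >= 10)
  vapply(.mackinnon_cv_c, function(b) {
    b[1] + b[2] / n_obs + b[3] / n_obs^2 + b[4] / n_obs^3
  }, numeric(1))
}

#' MacKinnon approximate p-value for the constant-only ADF statistic
#'
#' Approximate asymptotic p-value from MacKinnon's normal-quantile
#' polynomial: `p = pnorm(poly(tau))`, with the low-order polynomial for
#' statistics above the published switch point and the quadratic tail
#' polynomial below it.  Statistics beyond the published validity range
#' are clipped to p = 0 or p = 1.
#'
#' @param statistic The ADF t-statistic (finite scalar or vector).
#' @return p-value(s) in [0, 1], monotone increasing in the statistic.
#' @examples
#' mackinnon_pvalue(-6.979)
#' @export
mackinnon_pvalue <- function(statistic) {
  stopifnot(is.numeric(statistic), all(is.finite(statistic)))
  co <- .mackinnon_p_c
  vapply(statistic, function(tau) {
    if (tau > co$tau_max) return(1)
    if (tau < co$tau_min) return(0)
    z <- if (tau <= co$tau_star) {
      co$small[1] + co$small[2] * tau + co$small[3] * tau^2
    } else {
      co$large[1] + co$large[2] * tau + co$large[3] * tau^2 +
        co$large[4] * tau^3
    }
    stats::pnorm(z)
  }, numeric(1))
}

#' Augmented Dickey--Fuller unit-root test (constant only)
#'
#' Fits the ADF regression
#' `diff(y)_t = alpha + gamma * y_{t-1} + sum_j beta_j * diff(y)_{t-j} + e_t`
#' and tests `gamma = 0` (unit root) against `gamma < 0` (stationarity)
#' with the t-ratio of `gamma`.  The lag order is chosen by AIC over
#' `0..max_lag` on a common estimation sample (default
#' `max_lag = floor(12 * (n/100)^(1/4))`), then the model is refit with
#' the chosen order on the longest sample that order allows.  P-values
#' and critical values come from the MacKinnon response surfaces
#' ([mackinnon_pvalue()], [mackinnon_critical_values()]).
#'
#' @param series Numeric vector (length at least 10 after lag
#'   construction).
#' @param lags Fixed lag order; `NULL` (default) selects by AIC.
#' @param max_lag Largest lag order considered by the AIC search.
#' @return An object of class `adf_test` (also `htest`-printable): list
#'   with `statistic`, `p_value`, `lags_used`, `n_obs_used` and
#'   `critical_values`.  The identity
#'   `n_obs_used + lags_used + 1 == length(series)` holds.
#' @examples
#' set.seed(1)
#' adf_test(rnorm(100))
#' @export
adf_test <- function(series, lags = NULL, max_lag = NULL) {
  y <- as.numeric(series)
  n <- length(y)
  if (stats::sd(y) == 0) stop("degenerate input: series is constant")
  if (is.null(max_lag)) {
    # shrink the AIC search on short series so the regression keeps >= 10 obs
    max_lag <- max(0, min(floor(12 * (n / 100)^0.25), n - 12))
  }
  if (!is.null(lags)) max_lag <- lags
  if (n - max_lag - 1 < 10) stop("series too short after lag construction")
  dy <- diff(y)

  fit_one <- function(p, trim) {
    # regression sample: t = trim+1 .. n-1 in dy indexing
    rows <- (trim + 1L):(n - 1L)
    X <- cbind(1, y[rows])
    if (p > 0) for (j in 1:p) X <- cbind(X, dy[rows - j])
    yy <- dy[rows]
    f <- stats::lm.fit(X, yy)
    rss <- sum(f$residuals^2)
    k <- ncol(X)
    nn <- length(yy)
    list(fit = f, rss = rss, k = k, n = nn,
         aic = nn * log(rss / nn) + 2 * k)
  }

  if (is.null(lags)) {
    aics <- vapply(0:max_lag, function(p) fit_one(p, max_lag)$aic, numeric(1))
    p_sel <- which.min(aics) - 1L
  } else {
    p_sel <- as.integer(lags)
  }
  final <- fit_one(p_sel, p_sel)
  f <- final$fit
  sigma2 <- final$rss / (final$n - final$k)
  XtX_inv <- chol2inv(qr.R(f$qr))  # in pivoted column order
  pos <- which(f$qr$pivot == 2L)
  se_gamma <- sqrt(sigma2 * XtX_inv[pos, pos])
  stat <- f$coefficients[2] / se_gamma
  res <- list(statistic = unname(stat),
              p_value = mackinnon_pvalue(unname(stat)),
              lags_used = p_sel,
              n_obs_used = final$n,
              critical_values = mackinnon_critical_values(final$n))
  class(res) <- "adf_test"
  res
}

#' @export
print.adf_test <- function(x, ...) {
  cat("Augmented Dickey-Fuller test (constant, no trend)\n")
  cat(sprintf("  Test statistic            %.4f\n", x$statistic))
  cat(sprintf("  MacKinnon approx. p-value %.4g\n", x$p_value))
  cat(sprintf("  Lags used                 %d\n", x$lags_used))
  cat(sprintf("  Observations used         %d\n", x$n_obs_used))
  for (lv in names(x$critical_values)) {
    cat(sprintf("  Critical value (%s)      %.3f\n", lv, x$critical_values[[lv]]))
  }
  invisible(x)
}
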