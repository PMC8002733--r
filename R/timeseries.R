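#' Quarterly mean of a dated series
#'
#' Averages observations by calendar quarter (Q1 = Jan--Mar, Q2 =
#' Apr--Jun, ...).  The result covers every quarter from the first to the
#' last observed one; quarters with no observations are `NA` until
#' [fill_gaps()] is applied.
#'
#' @param series Data frame with columns `date` and a single value column
#'   (by default the second column, typically `lai`).
#' @param value Name of the value column; defaults to the first
#'   non-`date` column.
#' @return An object of class `quarterly_series`: a data frame with
#'   columns `year`, `quarter` and `value`, strictly increasing in time.
#' @export
quarterly_mean <- function(series, value = setdiff(names(series), "date")[1]) {
  stopifnot(is.data.frame(series), "date" %in% names(series),
            value %in% names(series))
  d <- as.Date(series$date)
  v <- as.numeric(series[[value]])
  yr <- as.integer(format(d, "%Y"))
  qt <- (as.integer(format(d, "%m")) - 1L) %/% 3L + 1L
  idx <- yr * 4L + (qt - 1L)
  full <- seq(min(idx), max(idx))
  means <- tapply(v, idx, mean)
  out <- data.frame(year = full %/% 4L, quarter = full %% 4L + 1L,
                    value = as.numeric(means[as.character(full)]))
  structure(out, class = c("quarterly_series", "data.frame"))
}

#' Fill empty quarters by neighbor averaging
#'
#' Each interior `NA` quarter is assigned the mean of the nearest
#' preceding and nearest following non-missing values (so a run of
#' consecutive gaps gets a single shared fill value).  Missing values at
#' either end cannot be filled and raise an error.
#'
#' @param series A [quarterly_mean()] result, or a plain numeric vector.
#' @return The input with every `NA` replaced; same class as the input.
#' @examples
#' fill_gaps(c(2, NA, 4))        # 2 3 4
#' fill_gaps(c(2, NA, NA, 6))    # 2 4 4 6
#' @export
fill_gaps <- function(series) {
  qs <- inherits(series, "quarterly_series")
  v <- if (qs) series$value else as.numeric(series)
  if (length(v) == 0) return(series)
  if (is.na(v[1]) || is.na(v[length(v)])) {
    stop("unfillable boundary: series starts or ends with a missing quarter")
  }
  miss <- which(is.na(v))
  obs <- which(!is.na(v))
  for (i in miss) {
    prev <- max(obs[obs < i])
    nxt <- min(obs[obs > i])
    v[i] <- (v[prev] + v[nxt]) / 2
  }
  if (qs) { series$value <- v; series } else v
}

#' Classical multiplicative seasonal decomposition
#'
#' Factors a positive seasonal series into trend x seasonal x residual by
#' classical moving-average decomposition: the trend is the centered
#' 2x`period` moving average, seasonal indices are per-season means of the
#' detrended ratios normalised to average 1, and the residual is
#' observation / (trend x seasonal).  Delegates to [stats::decompose()]
#' on a `ts` of frequency `period`.
#'
#' @param series A [quarterly_mean()] result (gap-filled) or a numeric
#'   vector; all values must be positive.
#' @param period Seasonal period; 4 for quarterly data.
#' @return An object of class `vi_decomposition`: list with numeric
#'   vectors `observed`, `trend`, `seasonal`, `residual` (trend and
#'   residual are `NA` at the `period/2` ends where the moving average is
#'   undefined) and `period`.
#' @export
decompose_multiplicative <- function(series, period = 4) {
  v <- if (inherits(series, "quarterly_series")) series$value else as.numeric(series)
  if (anyNA(v)) stop("series has missing values; apply fill_gaps() first")
  if (length(v) < 2 * period) stop("need at least two full periods")
  if (any(v <= 0)) stop("multiplicative decomposition requires positive values")
  dec <- stats::decompose(stats::ts(v, frequency = period), type = "multiplicative")
  structure(list(observed = v,
                 trend = as.numeric(dec$trend),
                 seasonal = as.numeric(dec$seasonal),
                 residual = as.numeric(dec$random),
                 figure = as.numeric(dec$figure),
                 period = period),
            class = "vi_decomposition")
}

#' @export
print.vi_decomposition <- function(x, ...) {
  cat(sprintf("Multiplicative decomposition: %d observations, period %d\n",
              length(x$observed), x$period))
  cat("  seasonal indices:", paste(sprintf("%.4f", x$figure), collapse = ", "), "\n")
  invisible(x)
}

#' Trailing rolling mean and standard deviation
#'
#' Computes the trailing-window mean and sample standard deviation used
#' in stationarity plots; the first `window - 1` positions are `NA`.
#'
#' @param series Numeric vector.
#' @param window Window length in observations (>= 2); the conventional
#'   choice for quarterly data is 4, one year.
#' @return A list with numeric vectors `mean` and `sd`, same length as
#'   the input.
#' @export
rolling_stats <- function(series, window = 4) {
  x <- as.numeric(series)
  n <- length(x)
  stopifnot(window >= 2)
  if (window > n) stop("window longer than series")
  m <- s <- rep(NA_real_, n)
  for (i in window:n) {
    w <- x[(i - window + 1L):i]
    m[i] <- mean(w)
    s[i] <- stats::sd(w)
  }
  list(mean = m, sd = s)
}
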