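test_that("quarterly means group by calendar quarter", {
  d <- data.frame(date = as.Date(c("2020-01-15", "2020-02-20", "2020-03-30")),
                  lai = c(4, 5, 6))
  q <- quarterly_mean(d)
  expect_equal(nrow(q), 1L)
  expect_equal(q$value, 5)
  expect_equal(q$quarter, 1L)

  const <- data.frame(date = seq(as.Date("2019-01-01"), as.Date("2020-12-31"), 10),
                      lai = 3)
  expect_true(all(quarterly_mean(const)$value == 3))

  # group-by oracle on a random series
  set.seed(1)
  r <- data.frame(date = as.Date("2018-01-01") + sample(0:730, 200),
                  lai = runif(200, 2, 7))
  q2 <- quarterly_mean(r)
  key <- paste0(format(r$date, "%Y"), "Q", (as.integer(format(r$date, "%m")) - 1) %/% 3 + 1)
  oracle <- tapply(r$lai, key, mean)
  got <- q2$value[!is.na(q2$value)]
  expect_equal(got, as.numeric(oracle[order(names(oracle))]))
  # quarters strictly increasing
  expect_true(all(diff(q2$year * 4 + q2$quarter) == 1))
})

test_that("gap filling averages nearest non-missing neighbors", {
  expect_equal(fill_gaps(c(2, NA, 4)), c(2, 3, 4))
  expect_equal(fill_gaps(c(1, 2, 3)), c(1, 2, 3))
  expect_equal(fill_gaps(c(2, NA, NA, 6)), c(2, 4, 4, 6))
  expect_equal(fill_gaps(c(1, NA, 3, NA, 7)), c(1, 2, 3, 5, 7))
  expect_error(fill_gaps(c(NA, 1, 2)), "boundary")
  expect_error(fill_gaps(c(1, 2, NA)), "boundary")
  q <- quarterly_mean(data.frame(date = as.Date(c("2020-02-01", "2020-08-01")),
                                 lai = c(2, 4)))
  filled <- fill_gaps(q)
  expect_s3_class(filled, "quarterly_series")
  expect_equal(filled$value, c(2, 3, 4))
})

test_that("multiplicative decomposition recovers structure and reconstructs", {
  # constant series: seasonal and residual identically 1
  dc <- decompose_multiplicative(rep(5, 16))
  expect_true(all(abs(dc$seasonal - 1) < 1e-12))
  expect_true(all(abs(dc$residual[!is.na(dc$residual)] - 1) < 1e-12))
  expect_true(all(abs(dc$trend[!is.na(dc$trend)] - 5) < 1e-12))

  # pure periodic pattern times a constant: indices proportional to pattern
  pattern <- c(0.8, 1.1, 1.3, 0.8)
  x <- rep(pattern, 6) * 10
  dp <- decompose_multiplicative(x)
  expect_equal(dp$figure, pattern / mean(pattern), tolerance = 1e-10)
  expect_equal(mean(dp$figure), 1, tolerance = 1e-12)

  # reconstruction identity wherever all components are defined
  set.seed(2)
  y <- exp(rnorm(24, 0, 0.2)) * rep(c(0.9, 1, 1.2, 0.9), 6)
  dd <- decompose_multiplicative(y)
  ok <- !is.na(dd$trend) & !is.na(dd$residual)
  expect_lt(max(abs(dd$trend[ok] * dd$seasonal[ok] * dd$residual[ok] - y[ok])), 1e-10)

  expect_error(decompose_multiplicative(c(1, 2, -1, 4, 1, 2, 3, 4, 1)), "positive")
  expect_error(decompose_multiplicative(rep(1, 7)), "two full periods")
  expect_error(decompose_multiplicative(c(1, NA, rep(1, 10))), "missing")
})

test_that("rolling statistics match a brute-force windowed computation", {
  rs <- rolling_stats(rep(4, 10), window = 4)
  expect_true(all(rs$mean[4:10] == 4))
  expect_true(all(rs$sd[4:10] == 0))
  expect_true(all(is.na(rs$mean[1:3])))

  x <- c(1, 5, 2, 8, 3)
  full <- rolling_stats(x, window = 5)
  expect_equal(full$mean[5], mean(x)); expect_equal(full$sd[5], sd(x))

  set.seed(3); y <- rnorm(30)
  got <- rolling_stats(y, window = 7)
  for (i in 7:30) {
    expect_equal(got$mean[i], mean(y[(i - 6):i]))
    expect_equal(got$sd[i], sd(y[(i - 6):i]))
  }
  expect_error(rolling_stats(1:3, window = 5), "longer than series")
  expect_error(rolling_stats(1:10, window = 1), "window")
})

test_that("ADF test reproduces an independent implementation's numbers", {
  # frozen oracle values computed with statsmodels 0.14.6 adfuller on the
  # identical series (R RNG, set.seed(5), rnorm(60))
  set.seed(5); x <- rnorm(60)
  auto <- adf_test(x)
  expect_equal(auto$statistic, -6.186660, tolerance = 1e-6)
  expect_equal(auto$lags_used, 0L)
  expect_equal(auto$p_value, 6.265e-08, tolerance = 1e-3)

  fixed <- adf_test(x, lags = 2)
  expect_equal(fixed$statistic, -4.1358941974, tolerance = 1e-9)
  expect_equal(fixed$p_value, 0.000844348, tolerance = 1e-6)
  expect_equal(fixed$n_obs_used, 57L)
})

test_that("ADF bookkeeping, invariances and degenerate input", {
  set.seed(6); x <- rnorm(80)
  a <- adf_test(x)
  expect_equal(a$n_obs_used + a$lags_used + 1L, length(x))
  # constant-only regression absorbs a level shift
  b <- adf_test(x + 100)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-10)
  expect_equal(a$lags_used, b$lags_used)
  expect_error(adf_test(rep(2, 50)), "constant")
  expect_error(adf_test(rnorm(8)), "too short")
})

test_that("MacKinnon critical values follow the response surface", {
  cv <- mackinnon_critical_values(26)
  expect_true(all(diff(cv) > 0))  # strictly increasing from 1% to 10%
  expect_equal(mackinnon_critical_values(1e9)[["5%"]], -2.862, tolerance = 5e-4)
  for (n in c(15, 50, 200, 1000)) {
    expect_true(all(diff(mackinnon_critical_values(n)) > 0))
  }
  expect_error(mackinnon_critical_values(5), "n_obs")
})

test_that("MacKinnon p-values are monotone and calibrated", {
  stats <- seq(-10, 2, by = 0.25)
  p <- mackinnon_pvalue(stats)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(mackinnon_pvalue(0), 0.9)
  expect_equal(mackinnon_pvalue(-25), 0)
  expect_equal(mackinnon_pvalue(3), 1)
  # canonical polynomial value at the Table-2 statistic, frozen from
  # statsmodels: 8.28528e-10 at -6.979.  The printed 8.281e-10 corresponds
  # to the unrounded statistic (~ -6.9791).
  expect_equal(mackinnon_pvalue(-6.979), 8.285278224549e-10, tolerance = 1e-9)
  expect_identical(signif(mackinnon_pvalue(-6.9791), 4), 8.281e-10)
})
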