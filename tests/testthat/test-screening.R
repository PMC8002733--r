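test_that("vegetation mask implements both threshold branches", {
  expect_true(vegetation_mask(0.50, 1.0))
  expect_true(vegetation_mask(0.38, 2.6))
  expect_false(vegetation_mask(0.38, 2.4))
  expect_false(vegetation_mask(0.10, 10))
  expect_true(vegetation_mask(0.36, 2.51))   # lower edge of the second branch
  expect_false(vegetation_mask(0.359, 10))
  expect_equal(vegetation_mask(c(0.5, 0.38, 0.1), c(1, 2.6, 10)),
               c(TRUE, TRUE, FALSE))
})

make_pixels <- function(n, seed, cloud_frac = 0.2) {
  set.seed(seed)
  # dense-canopy pixels plus some bare/sparse ones so the mask bites
  lai <- c(runif(round(n * 0.7), 3, 7), runif(n - round(n * 0.7), 0, 0.5))
  px <- simulate_canopy(lai, runif(n, 0.05, 0.3))
  px$cloud_flag <- runif(n) < cloud_frac
  px
}

test_that("scene aggregation averages only unmasked vegetation pixels", {
  cfg <- vi_config()
  one <- make_pixels(1, seed = 1, cloud_frac = 0)
  agg <- aggregate_scene(one, cfg)
  expect_equal(agg$red, one$red)
  expect_equal(agg$ndvi, ndvi(one))
  expect_equal(agg$n_pixels, 1L)

  two <- simulate_canopy(c(5, 6), c(0.1, 0.2))  # both dense vegetation
  two$cloud_flag <- c(TRUE, FALSE)
  agg2 <- aggregate_scene(two, cfg)
  expect_equal(agg2$nir, two$nir[2])

  # enumeration oracle over 100 random pixels
  px <- make_pixels(100, seed = 3)
  idx <- add_indices(px[, c("blue", "green", "red", "nir")], cfg)
  keep <- !px$cloud_flag & vegetation_mask(idx$ndvi, idx$grvi)
  agg3 <- aggregate_scene(px, cfg)
  expect_equal(agg3$n_pixels, sum(keep))
  expect_equal(agg3$savi, mean(idx$savi[keep]))
  expect_equal(agg3$red, mean(px$red[keep]))
  # VIs are averaged after per-pixel computation, not recomputed from means
  expect_false(isTRUE(all.equal(agg3$ndvi,
                                (agg3$nir - agg3$red) / (agg3$nir + agg3$red))))
})

test_that("scene aggregation commutes with pixel permutation", {
  px <- make_pixels(60, seed = 4)
  set.seed(5)
  perm <- px[sample(nrow(px)), ]
  expect_equal(aggregate_scene(px), aggregate_scene(perm))
})

test_that("scenes with no surviving pixels are rejected", {
  px <- make_pixels(10, seed = 6, cloud_frac = 0)
  px$cloud_flag <- TRUE
  expect_error(aggregate_scene(px), class = "saviopt_scene_rejected")
  bare <- simulate_canopy(rep(0, 5), runif(5, 0.05, 0.3))
  bare$cloud_flag <- FALSE
  expect_error(aggregate_scene(bare), class = "saviopt_scene_rejected")
})

test_that("LAI matching applies the 8-day window, 16-day fallback, rejection", {
  base <- as.Date("2020-06-15")
  ser <- function(offsets, lai) data.frame(date = base + offsets, lai = lai)

  m <- match_lai(base, ser(3, 5.2))
  expect_equal(m$lai, 5.2); expect_equal(m$window, 8)

  m <- match_lai(base, ser(c(12, 15), c(4, 6)))
  expect_equal(m$lai, 5); expect_equal(m$window, 16); expect_equal(m$n_used, 2L)

  m <- match_lai(base, ser(20, 5))
  expect_true(is.na(m$lai)); expect_equal(m$n_used, 0L)

  # precedence: an 8-day match never falls back to 16-day entries
  m <- match_lai(base, ser(c(5, 12), c(4, 9)))
  expect_equal(m$lai, 4); expect_equal(m$window, 8)

  # symmetric window: entries before the scene date count too
  m <- match_lai(base, ser(c(-6, 6), c(4, 6)))
  expect_equal(m$lai, 5); expect_equal(m$n_used, 2L)
})

test_that("same-day records merge by averaging, distinct dates pass through", {
  r <- data.frame(date = as.Date(c("2020-01-01", "2020-01-01", "2020-01-05")),
                  ndvi = c(0.8, 0.6, 0.7), lai = c(5, 7, 6))
  m <- merge_same_day(r)
  expect_equal(nrow(m), 2L)
  expect_equal(m$ndvi, c(0.7, 0.7))
  expect_equal(m$lai[1], 6)

  distinct <- data.frame(date = as.Date("2020-01-01") + 0:4, lai = 1:5)
  expect_equal(merge_same_day(distinct)$lai, as.numeric(1:5))

  # group-by-mean oracle on random duplicates
  set.seed(8)
  rr <- data.frame(date = as.Date("2020-01-01") + sample(0:9, 40, TRUE),
                   v = rnorm(40))
  m2 <- merge_same_day(rr)
  oracle <- tapply(rr$v, rr$date, mean)
  expect_equal(m2$v, as.numeric(oracle[as.character(m2$date)]))
})

field_batch <- function() {
  d <- function(x) as.Date(x)
  data.frame(
    site = paste0("s", 1:8),
    latitude = c(55, NA, 50, 48, 47, 46, 45, 45),
    longitude = c(-98, -98, -100, -101, -102, -103, -104, -104),
    lai = c(5.5, 6, 3.9, 4.06, 5, 6.5, 7, 8),
    lai_is_range = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    date_start = d(c("1994-07-01", "1994-07-01", "1994-07-01", "1994-07-01",
                     "1994-07-01", "1990-05-01", "1994-08-01", "1994-08-01")),
    date_end = d(c("1994-07-31", "1994-07-31", "1994-07-31", "1994-07-31",
                   "1994-07-31", "1990-07-15", "1994-08-31", "1994-08-31")),
    biome = "test"
  )
}

test_that("field-record cleaning applies each screen in order", {
  b <- field_batch()
  out <- clean_field_records(b)
  # s1 kept; s2 null lat; s3 lai < 4; s4 kept (4.06 >= 4); s5 range-valued;
  # s6 span > 31 days; s7/s8 same place+dates with different LAI -> both out
  expect_identical(out$site, c("s1", "s4"))

  expect_equal(nrow(clean_field_records(b[0, ])), 0L)

  # step-by-step filter oracle
  oracle <- b
  oracle <- oracle[!is.na(oracle$latitude), ]
  oracle <- oracle[!oracle$lai_is_range, ]
  oracle <- oracle[as.numeric(oracle$date_end - oracle$date_start) <= 31, ]
  oracle <- oracle[oracle$lai >= 4, ]
  key <- paste(oracle$latitude, oracle$longitude, oracle$date_start)
  dup <- names(which(tapply(oracle$lai, key, function(v) length(unique(v))) > 1))
  oracle <- oracle[!key %in% dup, ]
  expect_identical(out$site, oracle$site)
})

test_that("cleaning is idempotent and respects the sensor window", {
  b <- field_batch()
  once <- clean_field_records(b)
  expect_identical(clean_field_records(once), once)

  # a record outside the sensor window is dropped
  b2 <- b[b$site == "s1", ]
  b2$date_start <- as.Date("1975-07-01"); b2$date_end <- as.Date("1975-07-31")
  expect_equal(nrow(clean_field_records(b2)), 0L)
  # exact duplicates collapse to one row
  b3 <- rbind(b[b$site == "s1", ], b[b$site == "s1", ])
  expect_equal(nrow(clean_field_records(b3)), 1L)
})

test_that("the packaged field-site fixture survives cleaning intact", {
  path <- system.file("extdata", "glaifm_sites_synthetic.csv", package = "saviopt")
  rec <- read_field_records(path)
  expect_equal(nrow(rec), 8L)
  out <- clean_field_records(rec)
  expect_equal(nrow(out), 8L)      # all LAI >= 4.06, spans <= 1 month, in window
  expect_equal(min(out$lai), 4.06)
})
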