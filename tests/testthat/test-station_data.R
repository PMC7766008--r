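test_that("range screening flags out-of-range values and is idempotent", {
  s <- dplyr::bind_rows(
    make_series(c(2, 25, 1500, NA, 40), variable = "PM25"),
    make_series(c(101, 50, -0.5, 99.9, 0), variable = "RH")
  )
  scr <- screen_ranges(s, quiet = TRUE)
  expect_equal(scr$qc_flag[scr$variable == "PM25"],
               c("out_of_range", "valid", "out_of_range", "missing",
                 "valid"))
  expect_equal(scr$qc_flag[scr$variable == "RH"],
               c("out_of_range", "valid", "out_of_range", "valid",
                 "valid"))
  # values retained, never dropped or altered
  expect_equal(scr$value, s$value)
  # boundary values of the closed interval are in range
  b <- screen_ranges(make_series(c(3, 1000), variable = "PM10"),
                     quiet = TRUE)
  expect_equal(b$qc_flag, c("valid", "valid"))
  # idempotence
  expect_equal(screen_ranges(scr, quiet = TRUE), scr)
  # unknown variable is a configuration error
  expect_error(screen_ranges(make_series(1, variable = "O3"), quiet = TRUE),
               "no QC range")
})

test_that("manual exclusion list flags individual observations", {
  s <- make_series(c(10, 20, 30), variable = "PM25")
  excl <- s[2, c("station_id", "variable", "timestamp")]
  scr <- screen_ranges(s, exclusions = excl, quiet = TRUE)
  expect_equal(scr$qc_flag, c("valid", "visually_flagged", "valid"))
})

test_that("daily aggregation applies the inclusive 50% valid rule", {
  # 12 of 24 valid: mean computed; 11 of 24: missing
  v12 <- c(rep(40, 12), rep(NA, 12))
  v11 <- c(rep(40, 11), rep(NA, 13))
  d12 <- aggregate_daily(make_series(v12))
  d11 <- aggregate_daily(make_series(v11))
  expect_equal(d12$value, 40)
  expect_equal(d12$valid_fraction, 0.5)
  expect_true(is.na(d11$value))
  expect_equal(d11$n_valid, 11L)
})

test_that("windowed aggregation averages only window hours", {
  v <- rep(NA_real_, 24)
  v[11:16] <- c(200, 400, 600, 600, 400, 200)
  d <- aggregate_daily(make_series(v, variable = "GR"),
                       window_hours = 11:16)
  expect_equal(d$value, 400)
  expect_equal(d$valid_fraction, 1)
  expect_error(aggregate_daily(make_series(v), window_hours = integer()),
               "empty")
})

test_that("a constant series aggregates to that constant", {
  d <- aggregate_daily(make_series(rep(7.5, 48)))
  expect_equal(d$value, c(7.5, 7.5))
  expect_equal(nrow(d), 2)
})

test_that("midnight stamps belong to the previous day as hour 24", {
  s <- make_series(rep(10, 24))
  # stamps run 01:00 ... 00:00(+1); all 24 must land on one date
  d <- aggregate_daily(s)
  expect_equal(nrow(d), 1)
  expect_equal(d$n_valid, 24L)
})

test_that("wind direction averages as a vector mean", {
  # 350 and 10 degrees straddle north: arithmetic mean 180 is wrong
  v <- rep(c(350, 10), 12)
  d <- aggregate_daily(make_series(v, variable = "WD", height = 50))
  expect_equal(d$value, 0, tolerance = 1e-10)
})

test_that("linear gap-fill recovers exact and noisy relations", {
  set.seed(11)
  n <- 500
  ref_vals <- runif(n, 30, 90)
  ref <- make_series(ref_vals, variable = "RH", station = "P59")
  # identity relation
  tgt <- make_series(ref_vals, variable = "RH", station = "TW1")
  tgt$value[101:120] <- NA
  tgt$qc_flag[101:120] <- "missing"
  filled <- gap_fill_linear(tgt, ref, quiet = TRUE)
  expect_equal(filled$value[101:120], ref_vals[101:120], tolerance = 1e-8)
  expect_equal(unique(filled$qc_flag[101:120]), "filled")

  # exact affine relation: target = 2*ref + 5
  tgt2 <- make_series(2 * ref_vals + 5, variable = "RH", station = "TW1")
  tgt2$value[7] <- NA
  tgt2$qc_flag[7] <- "missing"
  ref10 <- ref
  filled2 <- gap_fill_linear(tgt2, ref10, quiet = TRUE)
  expect_equal(filled2$value[7], 2 * ref_vals[7] + 5, tolerance = 1e-8)

  # noisy relation: coefficients recovered within 3 standard errors
  a <- 3; b <- 0.8; sigma <- 1
  tgt3 <- make_series(a + b * ref_vals + rnorm(n, 0, sigma),
                      variable = "RH", station = "TW1")
  tgt3$value[201:250] <- NA
  tgt3$qc_flag[201:250] <- "missing"
  filled3 <- gap_fill_linear(tgt3, ref, quiet = TRUE)
  fit <- attr(filled3, "fit")
  se <- summary(fit)$coefficients[, "Std. Error"]
  expect_lt(abs(coef(fit)[[1]] - a), 3 * se[[1]])
  expect_lt(abs(coef(fit)[[2]] - b), 3 * se[[2]])

  # originally valid hours never altered
  ok <- tgt3$qc_flag == "valid"
  expect_equal(filled3$value[ok], tgt3$value[ok])
})

test_that("gap-fill refuses to extrapolate from too few pairs", {
  ref <- make_series(1:24, variable = "RH", station = "P59")
  tgt <- make_series(c(1:12, rep(NA, 12)), variable = "RH")
  expect_warning(out <- gap_fill_linear(tgt, ref, min_pairs = 100),
                 "not filling")
  expect_equal(out$value, tgt$value)
})

test_that("daily ratio is the mean of hourly ratios, not ratio of means", {
  pm25 <- make_series(rep(30, 24), variable = "PM25")
  pm10 <- make_series(rep(60, 24), variable = "PM10")
  expect_equal(daily_ratio(pm25, pm10)$value, 0.5)

  # asymmetric fixture: mean of ratios differs from ratio of means
  v25 <- c(rep(10, 12), rep(90, 12))
  v10 <- c(rep(100, 12), rep(100, 12))
  r <- daily_ratio(make_series(v25, variable = "PM25"),
                   make_series(v10, variable = "PM10"))
  mean_of_ratios <- mean(v25 / v10)
  ratio_of_means <- mean(v25) / mean(v10)
  expect_equal(r$value, mean_of_ratios)
  expect_equal(mean_of_ratios, ratio_of_means)  # equal here since PM10 const
  # now vary PM10 so the two statistics genuinely differ
  v10b <- c(rep(50, 12), rep(150, 12))
  r2 <- daily_ratio(make_series(v25, variable = "PM25"),
                    make_series(v10b, variable = "PM10"))
  expect_equal(r2$value, mean(v25 / v10b))
  expect_false(isTRUE(all.equal(r2$value, mean(v25) / mean(v10b))))
})

test_that("zero-PM10 hours are excluded and the valid rule applies to ratios", {
  v25 <- rep(30, 24)
  v10 <- rep(0, 24); v10[1:13] <- 60
  r <- daily_ratio(make_series(v25, variable = "PM25"),
                   make_series(v10, variable = "PM10"))
  expect_equal(r$n_valid, 13L)
  expect_equal(r$value, 0.5)
  # only 2 computable ratio hours out of 24 -> missing
  v10c <- rep(NA_real_, 24); v10c[1:2] <- 60
  r2 <- daily_ratio(make_series(v25, variable = "PM25"),
                    make_series(v10c, variable = "PM10"))
  expect_true(is.na(r2$value))
})
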