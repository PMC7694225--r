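test_that("time series validate years, values and units", {
  ts <- time_series(1961:1965, 1:5, "mg g-1")
  expect_s3_class(ts, "time_series")
  expect_equal(ts_unit(ts), "mg g-1")
  expect_error(time_series(c(1961, 1961), c(1, 2), "mg g-1"), "increasing")
  expect_error(time_series(1961:1962, c(1, NA), "mg g-1"), "finite")
  expect_error(time_series(1961, 1, "furlongs"), "unit")
})

test_that("interior year gaps are linearly interpolated and flagged", {
  ts <- time_series(c(1961, 1963, 1966), c(10, 14, 20), "mg g-1")
  filled <- fill_year_gaps(ts)
  expect_equal(filled$year, 1961:1966)
  expect_equal(filled$value, c(10, 12, 14, 16, 18, 20))
  expect_equal(attr(filled, "interpolated"), c(1962L, 1964L, 1965L))
})

test_that("time-series CSV I/O round-trips with the unit sidecar", {
  path <- withr::local_tempfile(fileext = ".csv")
  ts <- time_series(1961:1970, rnorm(10, 50, 5), "kg y-1 per capita")
  write_time_series(ts, path)
  back <- read_time_series(path)  # unit read from sidecar
  expect_equal(back$value, ts$value, tolerance = 1e-12)
  expect_equal(ts_unit(back), "kg y-1 per capita")
})

test_that("concentration series composes the fit with the fertilisation series", {
  fit <- anchored_dose_response()
  fert <- time_series(1961:1965, rep(50, 5), "kg N ha-1 y-1")
  conc <- gliadin_concentration_series(fert, fit)
  expect_equal(ts_unit(conc), "mg g-1")
  expect_true(all(conc$value == conc$value[1]))  # constant in, constant out

  # affine composition: linear ramp in, linear ramp out
  fert2 <- time_series(1961:1970, seq(10, 100, by = 10), "kg N ha-1 y-1")
  conc2 <- gliadin_concentration_series(fert2, fit)
  expect_equal(diff(conc2$value), rep(10 / 6, 9), tolerance = 1e-10)
  expect_equal(conc2$value[c(1, 10)], c(44, 59), tolerance = 1e-10)

  # endpoints of the historical fertilisation rise map onto ~44 and ~59
  fert3 <- time_series(c(1961, 2010), c(9.84, 93.8), "kg N ha-1 y-1")
  conc3 <- gliadin_concentration_series(fert3, fit)
  expect_equal(conc3$value, c(43.97, 57.97), tolerance = 1e-3)

  expect_error(gliadin_concentration_series(
    time_series(1961, 50, "mg g-1"), fit), "kg N ha-1")
})

test_that("intake chain carries the mg/g to kg dimensional factor", {
  conc <- time_series(1961:1963, rep(44, 3), "mg g-1")
  wheat <- time_series(1961:1963, rep(1000, 3), "kg y-1 per capita")
  intake <- gliadin_intake_series(conc, wheat)
  expect_equal(intake$value, rep(44, 3))  # 44 mg/g of 1000 kg is 44 kg
  expect_equal(ts_unit(intake), "kg y-1 per capita")

  # 44 mg/g at the historical ~54.5 kg consumption is ~2.4 kg per capita
  wheat2 <- time_series(1961:1963, rep(54.5, 3), "kg y-1 per capita")
  expect_equal(gliadin_intake_series(conc, wheat2)$value[1], 2.398, tolerance = 1e-3)

  # linearity in consumption; zero consumption gives zero intake
  wheat3 <- time_series(1961:1963, c(0, 50, 100), "kg y-1 per capita")
  i3 <- gliadin_intake_series(conc, wheat3)
  expect_equal(i3$value[1], 0)
  expect_equal(i3$value[3], 2 * i3$value[2])

  expect_error(gliadin_intake_series(conc,
    time_series(1981:1983, rep(50, 3), "kg y-1 per capita")), "disjoint")
})

test_that("with constant concentration the intake %-change equals the wheat %-change", {
  conc <- time_series(1961:2010, rep(50, 50), "mg g-1")
  wheat <- time_series(1961:2010, seq(54.5, 64.4, length.out = 50),
                       "kg y-1 per capita")
  intake <- gliadin_intake_series(conc, wheat)
  ch_i <- intake_change(intake, 1961, 2010)
  ch_w <- intake_change(wheat, 1961, 2010)
  expect_equal(ch_i$pct_change, ch_w$pct_change, tolerance = 1e-12)
})

test_that("endpoint changes and their identities are computed correctly", {
  s <- time_series(c(1961, 2010), c(2.4, 3.8), "kg y-1 per capita")
  ch <- intake_change(s, 1961, 2010)
  expect_equal(ch$delta, 1.4)
  expect_equal(ch$pct_change, 100 * 1.4 / 2.4)
  expect_equal(ch$delta, ch$intake_end - ch$intake_start)
  expect_equal(ch$pct_change, 100 * ch$delta / ch$intake_start)

  flat <- time_series(1961:1970, rep(3, 10), "kg y-1 per capita")
  ch0 <- intake_change(flat, 1961, 1970)
  expect_equal(ch0$delta, 0)
  expect_equal(ch0$pct_change, 0)

  expect_error(intake_change(s, 1960, 2010), "1960")
})

test_that("bootstrap SEs vanish for a zero-uncertainty fit and stabilise with reps", {
  fit <- anchored_dose_response()
  fert <- time_series(1961:2010, seq(9.84, 93.8, length.out = 50), "kg N ha-1 y-1")
  wheat <- time_series(1961:2010, seq(54.5, 64.4, length.out = 50),
                       "kg y-1 per capita")
  conc <- gliadin_concentration_series(fert, fit)
  intake <- gliadin_intake_series(conc, wheat)

  ch <- intake_change(intake, 1961, 2010, fit = fit, fert = fert,
                      wheat_intake = wheat, reps = 200, seed = 9)
  expect_equal(ch$delta_se, 0)
  expect_equal(ch$pct_se, 0)

  # with a fitted (uncertain) line the SE estimate converges in reps
  set.seed(40)
  d <- sample(seq(0, 360, 40), 120, replace = TRUE)
  y <- 42 + d / 6 + rnorm(120, 0, 8)
  f2 <- fit_dose_response(d, y)
  conc2 <- gliadin_concentration_series(fert, f2)
  intake2 <- gliadin_intake_series(conc2, wheat)
  se_1k <- intake_change(intake2, 1961, 2010, fit = f2, fert = fert,
                         wheat_intake = wheat, reps = 1000, seed = 1)$delta_se
  se_10k <- intake_change(intake2, 1961, 2010, fit = f2, fert = fert,
                          wheat_intake = wheat, reps = 10000, seed = 2)$delta_se
  expect_gt(se_1k, 0)
  expect_lt(abs(se_1k - se_10k) / se_10k, 0.10)

  expect_error(intake_change(intake, 1961, 2010, fit = fit, fert = fert,
                             wheat_intake = wheat, reps = 50), ">= 100")
})
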