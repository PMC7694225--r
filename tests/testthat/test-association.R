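test_that("collinear points give identical slopes for all three estimators", {
  f <- model2_fit(c(0, 1, 2), c(0, 2, 4))
  expect_equal(f$fits$slope, rep(2, 3))
  expect_equal(f$fits$intercept, rep(0, 3), tolerance = 1e-12)
  expect_equal(f$r, 1)
})

test_that("MA slope equals the leading-eigenvector oracle", {
  set.seed(50)
  for (i in 1:15) {
    n <- sample(10:60, 1)
    x <- rnorm(n, 0, runif(1, 0.5, 3))
    y <- runif(1, -2, 2) * x + rnorm(n, 0, runif(1, 0.2, 2))
    f <- model2_fit(x, y)
    ev <- eigen(stats::cov(cbind(x, y)), symmetric = TRUE)$vectors[, 1]
    expect_equal(f$fits$slope[f$fits$method == "MA"], ev[2] / ev[1],
                 tolerance = 1e-10)
    # SMA closed form: sign(r) * sd_y / sd_x
    expect_equal(abs(f$fits$slope[f$fits$method == "SMA"]), sd(y) / sd(x),
                 tolerance = 1e-12)
  }
})

test_that("MA and SMA slopes match brute-force loss minimisation over a slope grid", {
  set.seed(51)
  x <- rnorm(40); y <- 0.8 * x + rnorm(40, 0, 0.5)
  xc <- x - mean(x); yc <- y - mean(y)
  angles <- seq(-pi / 2 + 1e-3, pi / 2 - 1e-3, length.out = 20001)
  # MA minimises summed squared perpendicular distances
  perp <- vapply(angles, function(a) {
    b <- tan(a); sum((yc - b * xc)^2) / (1 + b^2)
  }, numeric(1))
  b_ma_grid <- tan(angles[which.min(perp)])
  f <- model2_fit(x, y)
  expect_equal(f$fits$slope[1], b_ma_grid, tolerance = 1e-3)
  # SMA minimises the summed product of absolute x- and y-residuals
  bgrid <- seq(0.1, 3, by = 1e-4)
  prodloss <- vapply(bgrid, function(b) sum(abs(yc - b * xc) * abs(xc - yc / b)),
                     numeric(1))
  expect_equal(f$fits$slope[2], bgrid[which.min(prodloss)], tolerance = 1e-3)
})

test_that("swapping x and y inverts the SMA slope", {
  set.seed(52)
  x <- runif(30, 30, 120); y <- 0.3 + 0.012 * x + rnorm(30, 0, 0.2)
  b_xy <- model2_fit(x, y)$fits$slope[2]
  b_yx <- model2_fit(y, x)$fits$slope[2]
  expect_equal(b_yx, 1 / b_xy, tolerance = 1e-12)
})

test_that("attenuation ordering holds: |MA| and |SMA| at least |OLS|", {
  set.seed(53)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    x <- rnorm(n); y <- runif(1, -1.5, 1.5) * x + rnorm(n, 0, runif(1, 0.1, 2))
    f <- model2_fit(x, y)$fits
    b <- setNames(f$slope, f$method)
    expect_gte(abs(b["SMA"]) + 1e-12, abs(b["OLS"]))
    expect_gte(abs(b["MA"]) + 1e-12, abs(b["OLS"]))
  }
})

test_that("all three fitted lines pass through the centroid", {
  set.seed(54)
  x <- runif(25, 0, 10); y <- 2 + 0.5 * x + rnorm(25)
  f <- model2_fit(x, y)
  for (i in 1:3) {
    expect_equal(f$fits$intercept[i] + f$fits$slope[i] * mean(x), mean(y),
                 tolerance = 1e-10)
  }
})

test_that("degenerate association inputs are rejected", {
  expect_error(model2_fit(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(model2_fit(c(1, 2), c(1, 2)), "3 points")
})

test_that("trajectory correlation works on the inner-joined years", {
  a <- time_series(1961:2000, seq(2, 4, length.out = 40), "kg y-1 per capita")
  expect_equal(trajectory_correlation(a, a)$r, 1)
  rev_b <- time_series(1961:2000, rev(seq(0.2, 1, length.out = 40)), "%")
  expect_equal(trajectory_correlation(a, rev_b)$r, -1)
  b <- time_series(1990:2020, seq(0.5, 1.2, length.out = 31), "%")
  res <- trajectory_correlation(a, b)
  expect_equal(res$n_overlap, 11L)
  expect_error(trajectory_correlation(a,
    time_series(2005:2010, 1:6, "%")), "3 overlapping")
  # differenced mode removes a shared monotone trend
  res_d <- trajectory_correlation(a, rev_b, diff = TRUE)
  expect_true(res_d$diff)
})

test_that("country panel CSV I/O validates its schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  panel <- generate_country_panel(generator_config(), seed = 5)
  write_country_panel(panel, path)
  back <- read_country_panel(path)
  expect_equal(back$cd_prevalence_pct, panel$cd_prevalence_pct, tolerance = 1e-12)
  bad <- data.frame(country_code = "ESP", wheat_intake_kg = 90)
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_country_panel(path2), "cd_prevalence_pct")
})
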