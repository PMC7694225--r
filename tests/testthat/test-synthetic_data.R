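test_that("generator output is a pure function of (config, seed)", {
  cfg <- generator_config(n_studies = 8)
  t1 <- generate_study_table(cfg, seed = 77)
  t2 <- generate_study_table(cfg, seed = 77)
  expect_identical(t1, t2)
  t3 <- generate_study_table(cfg, seed = 78)
  expect_false(identical(t1, t3))

  p1 <- generate_country_panel(cfg, seed = 77)
  p2 <- generate_country_panel(cfg, seed = 77)
  expect_identical(p1, p2)
})

test_that("default config encodes the study conditions", {
  cfg <- generator_config()
  expect_equal(cfg$n_studies, 47)
  expect_equal(cfg$n_countries, 38)
  expect_equal(cfg$fert_endpoints, c(9.84, 93.8))
  expect_equal(cfg$years, 1961:2010)
  expect_equal(cfg$slope_true, 1 / 6, tolerance = 1e-12)
  # reference contrast of the total-gliadin amplitude reproduces 44 -> 59
  a <- cfg$a[["total_gliadin"]]
  expect_equal(log1p(100 * a) - log1p(10 * a), log(59 / 44), tolerance = 1e-10)
  expect_error(generator_config(dose_grids = list(5)), "degenerate")
  expect_error(generator_config(tau2 = -1), "non-negative")
})

test_that("generated tables respect the configured design", {
  cfg <- generator_config()
  tab <- generate_study_table(cfg, seed = 1)
  expect_s3_class(tab, "study_table")  # constructor re-validated all rows
  expect_setequal(unique(tab$outcome), outcome_levels())
  expect_length(unique(tab$study_id), 47)
  expect_true(all(tab$n_control >= 3 & tab$n_control <= 10))
  expect_true(all(tab$sd_control / tab$mean_control < 0.45))
  expect_true(all(tab$mean_control > 0 & tab$mean_treatment > 0))
})

test_that("pooled lnRR per outcome recovers the configured expectation", {
  cfg <- generator_config()
  tab <- generate_study_table(cfg, seed = 13)
  fs <- forest_summary(effect_sizes(tab))
  for (i in seq_len(nrow(fs))) {
    mu_cfg <- cfg$mu_true[[fs$outcome[i]]]
    expect_lt(abs(fs$mu_hat[i] - mu_cfg) / fs$se[i], 2)
  }
})

test_that("a zero-amplitude generator pools to a null effect", {
  cfg <- generator_config(outcomes = c(total_gliadin = 0))
  zs <- vapply(1:5, function(s) {
    tab <- generate_study_table(cfg, seed = s)
    fit <- with(effect_sizes(tab), meta_reml(lnRR, variance, study = study_id))
    unname(fit$beta[1] / fit$se[1])
  }, numeric(1))
  expect_lt(max(abs(zs)), 4)
  expect_lt(abs(mean(zs)), 2)
})

test_that("generated annual series hit their configured endpoints and shape", {
  cfg <- generator_config()
  ser <- generate_time_series(cfg)
  fert <- ser$fertilisation
  expect_equal(fert$value[c(1, nrow(fert))], c(9.84, 93.8), tolerance = 1e-10)
  expect_true(all(diff(fert$value) > 0))  # strictly increasing
  expect_equal(fert$year, 1961:2010)

  # constant consumption profile yields a zero-variance series
  cfg_c <- generator_config(wheat_intake_profile = "constant")
  expect_equal(var(generate_time_series(cfg_c)$wheat_intake$value), 0)

  # prevalence logistic passes exactly through its anchors
  cd <- ser$cd_prevalence
  expect_equal(cd$value[cd$year == 1975], 0.2, tolerance = 1e-10)
  expect_equal(cd$value[cd$year == 2000], 1.0, tolerance = 1e-10)
  expect_true(all(diff(cd$value) > 0))
})

test_that("country panel size and slope recovery behave as configured", {
  cfg <- generator_config()
  panel <- generate_country_panel(cfg, seed = 3)
  expect_equal(nrow(panel), 38L)
  expect_true(all(panel$cd_prevalence_pct >= 0 & panel$cd_prevalence_pct <= 100))
  expect_true(all(panel$wheat_intake_kg >= 30 & panel$wheat_intake_kg <= 120))

  # noiseless panel: the MA fit recovers the configured slope exactly
  cfg0 <- generator_config(country_noise_sd = 0)
  p0 <- generate_country_panel(cfg0, seed = 4)
  f0 <- model2_fit(p0$wheat_intake_kg, p0$cd_prevalence_pct)
  expect_equal(f0$fits$slope[1], cfg0$country_slope, tolerance = 1e-10)

  # default noise: mean recovered slope within 10% over 200 replicates
  slopes <- vapply(1:200, function(s) {
    p <- generate_country_panel(cfg, seed = s)
    model2_fit(p$wheat_intake_kg, p$cd_prevalence_pct)$fits$slope[1]
  }, numeric(1))
  expect_lt(abs(mean(slopes) - cfg$country_slope) / cfg$country_slope, 0.10)
})
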