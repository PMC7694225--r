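test_that("symmetric and degenerate inputs pool as expected", {
  # two effects +d and -d with equal variances pool to zero
  f <- meta_reml(c(0.4, -0.4), c(0.02, 0.02))
  expect_equal(unname(f$beta[1]), 0, tolerance = 1e-10)

  # identical effects with equal variances: tau2 = 0, mu = that value
  f2 <- meta_reml(rep(0.25, 6), rep(0.01, 6))
  expect_equal(f2$tau2, 0, tolerance = 1e-8)
  expect_equal(unname(f2$beta[1]), 0.25, tolerance = 1e-10)

  expect_error(meta_reml(0.3, 0.01), "two effects")
  expect_error(meta_reml(c(0.3, 0.4), c(0, 0.01)), "positive sampling variances")
})

test_that("REML tau2 matches a dense grid-search oracle on random instances", {
  set.seed(20)
  for (i in 1:20) {
    inst <- random_meta_instance(k = sample(5:12, 1))
    fit <- meta_reml(inst$yi, inst$vi, multilevel = FALSE, tau2_max = 2)
    oracle <- grid_reml_tau2(inst$yi, inst$vi)
    expect_lt(abs(fit$tau2 - oracle), 1e-3)
  }
})

test_that("single-level fit agrees with metafor's REML implementation", {
  skip_if_not_installed("metafor")
  set.seed(21)
  for (i in 1:5) {
    inst <- random_meta_instance(k = 15)
    fit <- meta_reml(inst$yi, inst$vi, multilevel = FALSE)
    ref <- suppressWarnings(metafor::rma(inst$yi, inst$vi, method = "REML"))
    expect_lt(abs(unname(fit$beta[1]) - unname(as.numeric(ref$beta))), 1e-5)
    expect_lt(abs(unname(fit$se[1]) - ref$se), 1e-5)
    expect_lt(abs(fit$tau2 - ref$tau2), 1e-4)
  }
})

test_that("multilevel fit agrees with metafor's nested random-effects model", {
  skip_if_not_installed("metafor")
  set.seed(22)
  study <- rep(1:10, each = 3)
  u <- rnorm(10, 0, sqrt(0.04))[study]
  vi <- runif(30, 0.005, 0.05)
  yi <- 0.3 + u + rnorm(30, 0, sqrt(0.02 + vi))
  fit <- meta_reml(yi, vi, study = study)
  ref <- metafor::rma.mv(yi, vi, random = ~ 1 | study / esid,
                         data = data.frame(study = study, esid = 1:30))
  expect_lt(abs(unname(fit$beta[1]) - unname(as.numeric(ref$beta))), 1e-5)
  expect_lt(abs(unname(fit$se[1]) - ref$se), 1e-5)
  expect_lt(abs(fit$sigma2_study - ref$sigma2[1]), 1e-4)
  expect_lt(abs(fit$tau2 - ref$sigma2[2]), 1e-4)
})

test_that("pooled estimate interpolates between fixed-effect and unweighted means", {
  set.seed(23)
  inst <- random_meta_instance(k = 10)
  yi <- inst$yi; vi <- inst$vi
  fit <- meta_reml(yi, vi, multilevel = FALSE)

  # pooled mean must lie inside the convex hull of the effects
  expect_gte(unname(fit$beta[1]), min(yi))
  expect_lte(unname(fit$beta[1]), max(yi))

  # at tau2 = 0 the weights are 1/v (fixed-effect mean); as tau2 grows the
  # pooled mean approaches the unweighted mean
  pooled_at <- function(t2) sum(yi / (vi + t2)) / sum(1 / (vi + t2))
  expect_equal(pooled_at(0), sum(yi / vi) / sum(1 / vi))
  expect_equal(pooled_at(1e6), mean(yi), tolerance = 1e-4)
  expect_equal(unname(fit$beta[1]), pooled_at(fit$tau2), tolerance = 1e-10)
})

test_that("significance is exactly the CI-excludes-zero rule, either sign", {
  up <- meta_reml(rnorm(20, 0.5, 0.05), rep(0.002, 20))
  expect_true(significance_flag(up))
  down <- meta_reml(rnorm(20, -0.5, 0.05), rep(0.002, 20))
  expect_true(significance_flag(down))
  null <- meta_reml(c(-0.02, 0.3, -0.25, 0.01), rep(0.05, 4))
  expect_identical(significance_flag(null),
                   unname(null$ci_low[1] > 0 || null$ci_high[1] < 0))
  # flag must mirror the interval itself
  expect_true(null$ci_low[1] <= null$beta[1] && null$beta[1] <= null$ci_high[1])
})

test_that("forest summary returns one ordered row per surviving outcome", {
  tab <- generate_study_table(generator_config(), seed = 4)
  es <- effect_sizes(tab, min_obs = 30)
  fs <- forest_summary(es)
  expect_s3_class(fs, "forest_summary")
  expect_equal(fs$outcome, outcome_levels())
  expect_true(all(fs$k > 30))
  expect_true(all(fs$tau2 >= 0))
  expect_true(all(fs$ci_low <= fs$mu_hat & fs$mu_hat <= fs$ci_high))
  expect_identical(fs$significant, significance_flag(fs))

  # single-outcome table gives a one-row summary
  es1 <- es[es$outcome == "g_gliadin", ]
  expect_equal(nrow(forest_summary(es1)), 1L)
})
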