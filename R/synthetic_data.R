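# Dose grids (kg N ha-1 y-1) of the kind reported by the source
# fertilisation experiments; synthetic studies sample their design from
# this pool rather than from a continuous dose distribution.
dose_grid_pool <- function() {
  list(
    c(0, 120, 240, 360), c(0, 50, 80), c(0, 67), c(0, 70, 140),
    c(25, 50, 75), c(100, 200, 350), c(0, 100),
    c(0, 50, 100, 150, 200, 250, 300, 350, 400), c(0, 105, 165, 225),
    c(120, 140), c(0, 100, 140, 180), c(50, 100, 150, 250),
    c(0, 22.2, 66.7, 200), c(0, 120), c(0, 40, 80, 120, 160, 200, 240),
    c(0, 40, 80, 120), c(80, 120), c(0, 60, 90, 120, 150, 180, 210, 240),
    c(0, 90, 180, 270, 360, 450), c(0, 50, 100, 150), c(0, 50, 100),
    c(70, 120, 130, 160, 180, 200, 240), c(0, 180), c(0, 110),
    c(0, 220, 250), c(40, 60), c(0, 60, 90, 120), c(30, 40, 50, 70),
    c(40, 60, 120), c(0, 40, 120, 180, 200), c(84, 168), c(90, 150),
    c(168, 224, 280), c(220, 260), c(60, 90, 120), c(180, 240),
    c(0, 75, 150, 225))
}

# ISO-3 codes of the countries in the prevalence-vs-intake panel
country_codes <- function() {
  c("DZA", "ARG", "AUS", "AUT", "BFA", "BRA", "CZE", "DNK", "EGY", "EST",
    "CUB", "FIN", "DEU", "GRC", "HUN", "IND", "ISL", "IRN", "IRL", "ISR",
    "ITA", "JPN", "MEX", "NLD", "NZL", "NOR", "POL", "PRT", "RUS", "SVN",
    "ESP", "SWE", "CHE", "TUN", "TUR", "GBR", "USA", "URY")
}

# invert mu_ref = log((1 + 100 a)/(1 + 10 a)) for the relative-slope a
amplitude_from_ref <- function(mu_ref, ref_doses = c(10, 100)) {
  if (mu_ref == 0) return(0)
  if (mu_ref < 0 || mu_ref >= log(ref_doses[2] / ref_doses[1])) {
    stop("reference lnRR must lie in [0, log(", ref_doses[2] / ref_doses[1],
         "))", call. = FALSE)
  }
  f <- function(a) log1p(a * ref_doses[2]) - log1p(a * ref_doses[1]) - mu_ref
  stats::uniroot(f, c(1e-10, 1e3), tol = 1e-12)$root
}

#' Configuration of the synthetic-data generator
#'
#' Defines the ground truth of every synthetic input: the number of studies
#' and countries, per-outcome effect amplitudes, heterogeneity variances,
#' the dose-grid pool, the content-vs-dose anchor line and the FAO-style
#' series endpoints. Effect amplitudes are parameterised by the true lnRR
#' of a reference 10 -> 100 kg N ha^-1 y^-1 contrast; the generator converts
#' each to a relative slope `a_o` of the content line
#' `content = base_o * (1 + a_o * dose)` and derives `mu_true`, the exact
#' expected pooled lnRR under the configured dose-grid pool (enumerated over
#' all lowest-vs-higher contrasts), which parameter-recovery checks compare
#' against.
#'
#' @param n_studies Number of synthetic studies (default 47).
#' @param outcomes Named vector of reference lnRR values (10 -> 100 kg
#'   contrast) per outcome; defaults anchor total gliadin at
#'   `log(59/44)`.
#' @param dose_grids Pool of dose designs studies sample from.
#' @param anchor_doses,anchor_contents The two (dose, content) anchors of
#'   the total-gliadin line, default (10, 44) and (100, 59) mg g^-1.
#' @param baseline_content Named vector of outcome baselines at dose 0
#'   (mg g^-1, or arbitrary units for transcripts); the total-gliadin
#'   baseline is derived from the anchors and ignored here.
#' @param study_sd SD of the lognormal study-level baseline offset
#'   (between-study variation of absolute contents, shared across
#'   outcomes).
#' @param outcome_sd SD of the lognormal study-by-outcome baseline offset
#'   (assay/protocol differences in absolute level). Both baseline offsets
#'   are shared by the control and treatment arms of a contrast, so they
#'   scatter absolute contents without perturbing the response ratio; the
#'   `outcome_sd` default is calibrated so the pipeline's content-vs-dose
#'   fit has an expected R^2 of about 0.30.
#' @param arm_sd SD of the small independent lognormal dispersion drawn per
#'   arm (season/batch variation); unlike the baseline offsets this one
#'   does feed into the response ratio.
#' @param tau2 Contrast-level heterogeneity variance of lnRR.
#' @param sigma2_study Study-level random-intercept variance of lnRR.
#' @param cv_range Range of per-arm coefficients of variation.
#' @param n_range Range of per-arm replicate counts.
#' @param years Years of the annual series (default 1961:2010).
#' @param fert_endpoints Fertilisation-rate endpoints, kg N ha^-1 y^-1
#'   (default 9.84 and 93.8).
#' @param fert_shape `"logistic"` (default) or `"linear"` interpolation
#'   between the fertilisation endpoints.
#' @param wheat_intake_profile `"ramp"` (default) or `"constant"` per-capita
#'   wheat-and-derivatives consumption.
#' @param wheat_endpoints Consumption endpoints, kg y^-1 per capita.
#' @param cd_anchors Two (year, prevalence %) anchors of the logistic
#'   coeliac-prevalence trajectory, default 0.2% in 1975 and 1.0% in 2000.
#' @param cd_ceiling Ceiling of the prevalence logistic (%).
#' @param n_countries Size of the country panel (default 38).
#' @param country_intercept,country_slope,country_noise_sd Parameters of
#'   the country panel model
#'   `prevalence = a + b * intake + N(0, sd)`.
#' @return List of class `"generator_config"` including the derived
#'   amplitudes `a` and expected pooled effects `mu_true`.
#' @export
generator_config <- function(
    n_studies = 47,
    outcomes = c(total_gluten = 0.25, total_gliadin = log(59 / 44),
                 ab_gliadin = 0.30, g_gliadin = 0.25, w_gliadin = 0.30,
                 gliadin_transcript = 0.45),
    dose_grids = dose_grid_pool(),
    anchor_doses = c(10, 100), anchor_contents = c(44, 59),
    baseline_content = c(total_gluten = 100, total_gliadin = NA,
                         ab_gliadin = 20, g_gliadin = 12, w_gliadin = 5,
                         gliadin_transcript = 100),
    study_sd = 0.15, outcome_sd = 0.30, arm_sd = 0.05,
    tau2 = 0.01, sigma2_study = 0.005,
    cv_range = c(0.05, 0.2), n_range = c(3L, 10L),
    years = 1961:2010,
    fert_endpoints = c(9.84, 93.8),
    fert_shape = c("logistic", "linear"),
    wheat_intake_profile = c("ramp", "constant"),
    wheat_endpoints = c(54.5, 64.4),
    cd_anchors = list(c(1975, 0.2), c(2000, 1.0)),
    cd_ceiling = 1.2,
    n_countries = 38,
    country_intercept = 0.3, country_slope = 0.012, country_noise_sd = 0.2) {
  fert_shape <- match.arg(fert_shape)
  wheat_intake_profile <- match.arg(wheat_intake_profile)
  if (n_studies < 1) stop("n_studies must be >= 1", call. = FALSE)
  if (length(dose_grids) == 0 || any(vapply(dose_grids, length, 1L) < 2)) {
    stop("degenerate dose-grid pool: every grid needs >= 2 dose levels", call. = FALSE)
  }
  if (any(!names(outcomes) %in% outcome_levels())) {
    stop("unknown outcome in config", call. = FALSE)
  }
  if (tau2 < 0 || sigma2_study < 0 || study_sd < 0 || outcome_sd < 0 ||
      arm_sd < 0 || country_noise_sd < 0) {
    stop("variances must be non-negative", call. = FALSE)
  }

  # total-gliadin baseline and slope implied by the anchor line
  slope_true <- diff(anchor_contents) / diff(anchor_doses)
  baseline_content["total_gliadin"] <-
    anchor_contents[1] - slope_true * anchor_doses[1]

  a <- vapply(outcomes, amplitude_from_ref, numeric(1), ref_doses = anchor_doses)

  # exact expected pooled lnRR under the grid pool (uniform grid choice,
  # lowest-vs-each-higher contrasts)
  mu_true <- vapply(a, function(ao) {
    th <- unlist(lapply(dose_grids, function(g) {
      g <- sort(g)
      log1p(ao * g[-1]) - log1p(ao * g[1])
    }))
    mean(th)
  }, numeric(1))

  structure(list(
    n_studies = n_studies, outcomes = outcomes, a = a, mu_true = mu_true,
    dose_grids = dose_grids, anchor_doses = anchor_doses,
    anchor_contents = anchor_contents, slope_true = slope_true,
    baseline_content = baseline_content, study_sd = study_sd,
    outcome_sd = outcome_sd, arm_sd = arm_sd,
    tau2 = tau2, sigma2_study = sigma2_study,
    cv_range = cv_range, n_range = as.integer(n_range), years = years,
    fert_endpoints = fert_endpoints, fert_shape = fert_shape,
    wheat_intake_profile = wheat_intake_profile,
    wheat_endpoints = wheat_endpoints,
    cd_anchors = cd_anchors, cd_ceiling = cd_ceiling,
    n_countries = n_countries, country_intercept = country_intercept,
    country_slope = country_slope, country_noise_sd = country_noise_sd),
    class = "generator_config")
}

# draw a positive observed arm mean (truncation essentially never binds at
# the configured CV/n ranges)
rmean_pos <- function(m, sd_mean) {
  repeat {
    x <- stats::rnorm(1, m, sd_mean)
    if (x > 0) return(x)
  }
}

#' Generate a synthetic study-extraction table
#'
#' Emulates the structure of a fertilisation-experiment extraction table
#' with known ground truth. Each study draws a dose design from the grid
#' pool and lognormal baseline offsets at the study level (`study_sd`,
#' shared across outcomes) and the study-by-outcome level (`outcome_sd`).
#' Both offsets multiply the control and treatment arms of a contrast
#' alike, emulating between-study assay and genotype differences in
#' absolute contents that cancel in the response ratio. For outcome `o`
#' the true content at dose `d` is `base_o * (1 + a_o * d)` times these
#' offsets, so the true contrast effect of a lowest-vs-higher pair is
#' `log((1 + a_o d_t)/(1 + a_o d_c))` plus a study-level random intercept
#' (variance `sigma2_study`), a contrast-level deviation (variance `tau2`)
#' and a small independent per-arm dispersion (`arm_sd`). Observed arm
#' means are drawn
#' from the sampling distribution implied by the arm SD (CV uniform in
#' `cv_range`) and replicate count (uniform in `n_range`); each study's
#' control arm is drawn once per outcome and shared across its contrasts.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A [study_table()].
#' @export
generate_study_table <- function(config, seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  varieties <- c("Shiraz", "Neepawa", "Soissons", "Hereward", "Batis",
                 "Skagen", "Zebra", "Tybalt", "Capo", "Kadett", "Quartzo",
                 "Bobwhite")
  rows <- vector("list", config$n_studies * length(config$outcomes))
  ri <- 0L
  for (i in seq_len(config$n_studies)) {
    grid <- sort(config$dose_grids[[sample.int(length(config$dose_grids), 1L)]])
    b_i <- stats::rnorm(1, 0, config$study_sd)
    genotype <- sample(varieties, 1L)
    sid <- sprintf("S%02d", i)
    for (oc in names(config$outcomes)) {
      a_o <- config$a[[oc]]
      base_o <- config$baseline_content[[oc]]
      u_io <- stats::rnorm(1, 0, sqrt(config$sigma2_study))
      c_io <- stats::rnorm(1, 0, config$outcome_sd)
      d0 <- grid[1]
      base_io <- base_o * exp(b_i + c_io)
      M_c <- base_io * (1 + a_o * d0) * exp(stats::rnorm(1, 0, config$arm_sd))
      n_c <- sample(seq(config$n_range[1], config$n_range[2]), 1L)
      S_c <- stats::runif(1, config$cv_range[1], config$cv_range[2]) * M_c
      X_c <- rmean_pos(M_c, S_c / sqrt(n_c))
      for (dt in grid[-1]) {
        w <- stats::rnorm(1, 0, sqrt(config$tau2))
        theta <- u_io + w + stats::rnorm(1, 0, config$arm_sd)
        M_t <- base_io * (1 + a_o * dt) * exp(theta)
        n_t <- sample(seq(config$n_range[1], config$n_range[2]), 1L)
        S_t <- stats::runif(1, config$cv_range[1], config$cv_range[2]) * M_t
        X_t <- rmean_pos(M_t, S_t / sqrt(n_t))
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          study_id = sid, outcome = oc, dose_control = d0, dose_treatment = dt,
          mean_control = X_c, sd_control = S_c, n_control = n_c,
          mean_treatment = X_t, sd_treatment = S_t, n_treatment = n_t,
          genotype = genotype, stringsAsFactors = FALSE)
      }
    }
  }
  study_table(do.call(rbind, rows[seq_len(ri)]))
}

#' Generate the FAO-style annual input series
#'
#' Produces the three deterministic annual series the intake chain and the
#' co-trajectory comparison need: the wheat fertilisation rate
#' (monotone logistic or linear between the configured endpoints, default
#' 9.84 -> 93.8 kg N ha^-1 y^-1 over 1961-2010), per-capita wheat and
#' derivatives consumption (linear ramp or constant), and a logistic
#' coeliac-prevalence trajectory passing exactly through the configured
#' anchors (default 0.2% in 1975 rising 5-fold to 1.0% by 2000).
#'
#' @param config A [generator_config()].
#' @param seed Unused (the series are deterministic); kept for interface
#'   symmetry with the other generators.
#' @return List of three [time_series()]: `fertilisation`, `wheat_intake`,
#'   `cd_prevalence`.
#' @export
generate_time_series <- function(config, seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  yrs <- config$years
  n <- length(yrs)
  lo <- config$fert_endpoints[1]
  hi <- config$fert_endpoints[2]
  fert_vals <- if (config$fert_shape == "linear") {
    seq(lo, hi, length.out = n)
  } else {
    raw <- stats::plogis((yrs - stats::median(yrs)) / 8)
    lo + (hi - lo) * (raw - raw[1]) / (raw[n] - raw[1])
  }
  wheat_vals <- if (config$wheat_intake_profile == "constant") {
    rep(config$wheat_endpoints[1], n)
  } else {
    seq(config$wheat_endpoints[1], config$wheat_endpoints[2], length.out = n)
  }
  # logistic with ceiling K through the two (year, prevalence) anchors
  K <- config$cd_ceiling
  a1 <- config$cd_anchors[[1]]
  a2 <- config$cd_anchors[[2]]
  l1 <- log(K / a1[2] - 1)
  l2 <- log(K / a2[2] - 1)
  s <- (a1[1] - a2[1]) / (l2 - l1)
  t0 <- a1[1] + s * l1
  cd_vals <- K * stats::plogis((yrs - t0) / s)

  list(fertilisation = time_series(yrs, fert_vals, "kg N ha-1 y-1"),
       wheat_intake = time_series(yrs, wheat_vals, "kg y-1 per capita"),
       cd_prevalence = time_series(yrs, cd_vals, "%"))
}

#' Generate a synthetic country panel
#'
#' Country-level (wheat intake, coeliac prevalence) pairs with known ground
#' truth: intake uniform on 30-120 kg y^-1 per capita, prevalence
#' `a + b * intake + N(0, sd)` (floored at 0.01%), labelled with ISO-3
#' codes.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return data.frame of class `"country_panel"` with columns
#'   `country_code`, `wheat_intake_kg`, `cd_prevalence_pct`.
#' @export
generate_country_panel <- function(config, seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_countries < 3) stop("need at least 3 countries", call. = FALSE)
  set.seed(seed)
  codes <- country_codes()
  if (config$n_countries <= length(codes)) {
    codes <- codes[seq_len(config$n_countries)]
  } else {
    codes <- c(codes, sprintf("X%02d", seq_len(config$n_countries - length(codes))))
  }
  intake <- stats::runif(config$n_countries, 30, 120)
  prev <- config$country_intercept + config$country_slope * intake +
    stats::rnorm(config$n_countries, 0, config$country_noise_sd)
  prev <- pmax(prev, 0.01)
  df <- data.frame(country_code = codes, wheat_intake_kg = intake,
                   cd_prevalence_pct = prev, stringsAsFactors = FALSE)
  class(df) <- c("country_panel", "data.frame")
  df
}
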