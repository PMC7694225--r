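#' Predicted gliadin concentration series from a fertilisation series
#'
#' Pushes an annual fertilisation series (kg N ha^-1 y^-1) through a
#' dose-response fit to obtain the implied grain gliadin concentration
#' (mg g^-1) year by year.
#'
#' @param fert A [time_series()] with unit `kg N ha-1 y-1`.
#' @param fit A [fit_dose_response()] / [anchored_dose_response()] fit.
#' @param allow_extrapolation Passed to [predict.dose_response()].
#' @return A `time_series` in `mg g-1`.
#' @export
gliadin_concentration_series <- function(fert, fit, allow_extrapolation = FALSE) {
  stopifnot(inherits(fert, "time_series"), inherits(fit, "dose_response"))
  if (ts_unit(fert) != "kg N ha-1 y-1") {
    stop("fertilisation series must be in kg N ha-1 y-1, got '", ts_unit(fert), "'",
         call. = FALSE)
  }
  conc <- predict(fit, fert$value, allow_extrapolation = allow_extrapolation)
  time_series(fert$year, conc, "mg g-1")
}

#' Per-capita gliadin intake from concentration and wheat consumption
#'
#' Combines a gliadin concentration series (mg g^-1, i.e. g per kg of wheat
#' product) with a per-capita wheat-and-derivatives consumption series
#' (kg y^-1) on their common years:
#' `intake_kg = concentration_mg_per_g * wheat_kg / 1000`.
#'
#' @param conc A `time_series` in `mg g-1`.
#' @param wheat_intake A `time_series` in `kg y-1 per capita`.
#' @return A `time_series` of per-capita gliadin intake, `kg y-1 per capita`,
#'   on the inner-joined years.
#' @export
gliadin_intake_series <- function(conc, wheat_intake) {
  stopifnot(inherits(conc, "time_series"), inherits(wheat_intake, "time_series"))
  if (ts_unit(conc) != "mg g-1") {
    stop("concentration series must be in mg g-1", call. = FALSE)
  }
  if (ts_unit(wheat_intake) != "kg y-1 per capita") {
    stop("wheat-intake series must be in kg y-1 per capita", call. = FALSE)
  }
  common <- intersect(conc$year, wheat_intake$year)
  if (length(common) == 0L) stop("series share no years (disjoint ranges)", call. = FALSE)
  ci <- conc$value[match(common, conc$year)]
  wi <- wheat_intake$value[match(common, wheat_intake$year)]
  time_series(common, ci * wi / 1000, "kg y-1 per capita")
}

#' Change in per-capita intake between two years, with bootstrap SEs
#'
#' Computes the absolute and relative change of an annual series between
#' two endpoint years. When the series was derived through a dose-response
#' fit, supplying `fit`, `fert` and `wheat_intake` propagates the fit's
#' coefficient uncertainty by parametric bootstrap: coefficient draws from
#' `N(coef, vcov)` are pushed through the whole
#' fertilisation -> concentration -> intake chain and the endpoint change is
#' recomputed per draw. A fit with zero coefficient covariance (e.g. the
#' anchored two-point line) therefore yields zero SEs.
#'
#' @param series A [time_series()] (typically per-capita gliadin intake).
#' @param start_year,end_year Endpoint years; both must be present.
#' @param fit,fert,wheat_intake Optional: the dose-response fit and the two
#'   input series, enabling the bootstrap. All three must be given together.
#' @param reps Bootstrap replicates (>= 100 when SEs are requested).
#' @param seed Optional RNG seed for the bootstrap.
#' @return Object of class `"intake_change"`: `start_year`, `end_year`,
#'   `intake_start`, `intake_end`, `delta` (= end - start), `pct_change`
#'   (= 100 * delta / start), and when bootstrapped `delta_se`, `pct_se`,
#'   `reps`, `seed` (otherwise SEs are `NA`).
#' @export
intake_change <- function(series, start_year, end_year,
                          fit = NULL, fert = NULL, wheat_intake = NULL,
                          reps = 1000, seed = NULL) {
  stopifnot(inherits(series, "time_series"))
  for (yr in c(start_year, end_year)) {
    if (!yr %in% series$year) stop("year ", yr, " not present in series", call. = FALSE)
  }
  v0 <- series$value[series$year == start_year]
  v1 <- series$value[series$year == end_year]
  delta <- v1 - v0
  pct <- 100 * delta / v0

  delta_se <- pct_se <- NA_real_
  boot <- !is.null(fit)
  if (boot) {
    if (is.null(fert) || is.null(wheat_intake)) {
      stop("bootstrap needs fit, fert and wheat_intake together", call. = FALSE)
    }
    if (reps < 100) stop("reps must be >= 100 when SEs are requested", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    Sigma <- vcov(fit)
    cf <- coef(fit)
    draws <- if (all(Sigma == 0)) {
      matrix(rep(cf, each = reps), nrow = reps,
             dimnames = list(NULL, names(cf)))
    } else {
      # N(cf, Sigma) via Cholesky; pivoting tolerates a singular covariance
      ch <- suppressWarnings(chol(Sigma, pivot = TRUE))
      piv <- attr(ch, "pivot")
      Z <- matrix(stats::rnorm(reps * 2), reps, 2) %*% ch[, order(piv), drop = FALSE]
      sweep(Z, 2, cf, "+")
    }
    x <- if (fit$form == "log_dose") log1p(fert$value) else fert$value
    common <- intersect(fert$year, wheat_intake$year)
    ix_f <- match(common, fert$year)
    ix_w <- match(common, wheat_intake$year)
    i0 <- match(start_year, common)
    i1 <- match(end_year, common)
    if (is.na(i0) || is.na(i1)) {
      stop("endpoint years missing from the bootstrap input series", call. = FALSE)
    }
    wv <- wheat_intake$value[ix_w]
    xs <- x[ix_f]
    stat <- vapply(seq_len(reps), function(r) {
      conc_r <- draws[r, 1] + draws[r, 2] * xs
      intake_r <- conc_r * wv / 1000
      d <- intake_r[i1] - intake_r[i0]
      c(d, 100 * d / intake_r[i0])
    }, numeric(2))
    delta_se <- stats::sd(stat[1, ])
    pct_se <- stats::sd(stat[2, ])
  }

  structure(list(start_year = start_year, end_year = end_year,
                 intake_start = v0, intake_end = v1,
                 delta = delta, pct_change = pct,
                 delta_se = delta_se, pct_se = pct_se,
                 reps = if (boot) reps else NA_integer_,
                 seed = if (boot) seed else NULL,
                 unit = ts_unit(series)),
            class = "intake_change")
}

#' @export
print.intake_change <- function(x, digits = 3, ...) {
  cat(sprintf("Intake change %d -> %d [%s]\n", x$start_year, x$end_year, x$unit))
  cat(sprintf("  %.*g -> %.*g  (delta %+.*g", digits, x$intake_start,
              digits, x$intake_end, digits, x$delta))
  if (is.finite(x$delta_se)) cat(sprintf(" +/- %.*g", digits, x$delta_se))
  cat(sprintf(", %+.*g%%", digits, x$pct_change))
  if (is.finite(x$pct_se)) cat(sprintf(" +/- %.*g%%", digits, x$pct_se))
  cat(")\n")
  if (is.finite(x$delta_se)) {
    cat(sprintf("  SEs from %d parametric bootstrap draws of the dose-response coefficients\n",
                x$reps))
  }
  invisible(x)
}
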