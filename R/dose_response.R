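#' Fit the dose-response of grain gliadin content on fertilisation rate
#'
#' Ordinary (optionally weighted) least-squares regression of a grain or
#' flour response (mg g^-1) on the nitrogen-fertilisation rate
#' (kg N ha^-1 y^-1). `form = "linear"` regresses on the raw rate;
#' `form = "log_dose"` regresses on `log1p(dose)` (doses of zero occur in
#' control arms, so the shifted logarithm is used).
#'
#' @param dose Non-negative fertilisation rates, at least 3 points with
#'   some variation.
#' @param response Response values (e.g. total gliadin content, mg g^-1).
#' @param weights Optional positive case weights.
#' @param form `"linear"` (default) or `"log_dose"`.
#' @return Object of class `"dose_response"`: `slope`, `intercept`, `r2`,
#'   `p_value` (slope Wald test), `form`, the underlying `lm` fit, and the
#'   observed dose range used by the extrapolation guard of
#'   [predict.dose_response()].
#' @seealso [anchored_dose_response()] for the two-point exact fit,
#'   [meta_regression()] for the lnRR-on-dose sensitivity analysis.
#' @export
fit_dose_response <- function(dose, response, weights = NULL,
                              form = c("linear", "log_dose")) {
  form <- match.arg(form)
  dose <- as.numeric(dose)
  response <- as.numeric(response)
  if (length(dose) < 3L) stop("need at least 3 points", call. = FALSE)
  if (length(response) != length(dose)) stop("dose and response lengths differ", call. = FALSE)
  if (any(dose < 0)) stop("doses must be non-negative", call. = FALSE)
  if (stats::var(dose) == 0) stop("all doses identical: no moderator variation", call. = FALSE)

  x <- if (form == "log_dose") log1p(dose) else dose
  df <- data.frame(x = x, y = response)
  fit <- if (is.null(weights)) stats::lm(y ~ x, data = df)
  else stats::lm(y ~ x, data = df, weights = weights)
  # summary.lm warns on an exactly collinear fit; the R^2/p it returns are
  # still what we want to report
  sm <- suppressWarnings(summary(fit))

  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = sm$r.squared,
    p_value = sm$coefficients[2, 4],
    form = form,
    lm = fit,
    dose_range = range(dose),
    n = length(dose)), class = "dose_response")
}

#' Exact two-point dose-response line
#'
#' The line through two (dose, content) anchor points, used to propagate a
#' known concentration change through the intake chain. The default anchors
#' are 44 mg g^-1 at 10 kg N ha^-1 y^-1 and 59 mg g^-1 at
#' 100 kg N ha^-1 y^-1 (slope 1/6). The fit is exact, so its coefficient
#' covariance is zero and bootstrap uncertainty propagated from it vanishes.
#'
#' @param doses Two distinct doses.
#' @param contents The contents (mg g^-1) at those doses.
#' @return A `"dose_response"` object with `r2 = 1` and zero coefficient
#'   covariance.
#' @export
anchored_dose_response <- function(doses = c(10, 100), contents = c(44, 59)) {
  stopifnot(length(doses) == 2L, length(contents) == 2L, doses[1] != doses[2])
  slope <- diff(contents) / diff(doses)
  structure(list(
    slope = slope,
    intercept = contents[1] - slope * doses[1],
    r2 = 1, p_value = NA_real_, form = "linear", lm = NULL,
    dose_range = range(doses), n = 2L), class = "dose_response")
}

#' @export
coef.dose_response <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
vcov.dose_response <- function(object, ...) {
  if (is.null(object$lm)) {
    matrix(0, 2, 2, dimnames = list(c("intercept", "slope"), c("intercept", "slope")))
  } else {
    v <- stats::vcov(object$lm)
    dimnames(v) <- list(c("intercept", "slope"), c("intercept", "slope"))
    v
  }
}

#' Predict gliadin content at a fertilisation rate
#'
#' Point prediction (with optional standard error of the conditional mean)
#' from a [fit_dose_response()] or [anchored_dose_response()] fit. Requested
#' doses must lie in `[0, 1.5 * max(observed dose)]` unless
#' `allow_extrapolation = TRUE`.
#'
#' @param object A `dose_response` fit.
#' @param dose Doses at which to predict (kg N ha^-1 y^-1).
#' @param se Return standard errors alongside the predictions?
#' @param allow_extrapolation Disable the extrapolation guard.
#' @param ... Unused.
#' @return Numeric vector of predictions, or if `se = TRUE` a data.frame
#'   with columns `dose`, `fit`, `se`.
#' @export
predict.dose_response <- function(object, dose, se = FALSE,
                                  allow_extrapolation = FALSE, ...) {
  dose <- as.numeric(dose)
  hi <- 1.5 * object$dose_range[2]
  if (!allow_extrapolation && (any(dose < 0) || any(dose > hi))) {
    stop("dose outside the prediction guard [0, ", format(hi),
         "]; set allow_extrapolation = TRUE to override", call. = FALSE)
  }
  x <- if (object$form == "log_dose") log1p(dose) else dose
  yhat <- object$intercept + object$slope * x
  if (!se) return(yhat)
  se_fit <- if (is.null(object$lm)) {
    rep(0, length(dose))
  } else {
    stats::predict(object$lm, newdata = data.frame(x = x), se.fit = TRUE)$se.fit
  }
  data.frame(dose = dose, fit = yhat, se = se_fit)
}

#' Alias for predicting gliadin content
#'
#' Convenience wrapper around [predict.dose_response()] matching the
#' pipeline vocabulary.
#'
#' @inheritParams predict.dose_response
#' @param fit A `dose_response` fit.
#' @return See [predict.dose_response()].
#' @export
predict_gliadin <- function(fit, dose, se = FALSE, allow_extrapolation = FALSE) {
  predict(fit, dose = dose, se = se, allow_extrapolation = allow_extrapolation)
}

#' @export
print.dose_response <- function(x, digits = 4, ...) {
  cat(sprintf("Dose-response fit (%s form, n = %d)\n", x$form, x$n))
  cat(sprintf("  content = %.*g + %.*g * %s\n", digits, x$intercept, digits,
              x$slope, if (x$form == "linear") "dose" else "log1p(dose)"))
  cat(sprintf("  R^2 = %.*g", digits, x$r2))
  if (is.finite(x$p_value)) cat(sprintf(", slope p = %.*g", digits, x$p_value))
  cat("\n")
  invisible(x)
}

#' REML meta-regression of effect sizes on a dose moderator
#'
#' The sensitivity analysis companion to [fit_dose_response()]: regresses
#' log response ratios on a study-level moderator (by default the dose
#' increment of the contrast, kg N ha^-1 y^-1) under the random-effects
#' model, weighting by `1 / (v + tau2)` with `tau2` estimated by REML.
#'
#' @param effects An [effect_sizes()] data.frame (optionally filtered to one
#'   outcome before calling).
#' @param moderator Column name of the moderator; default `"dose_delta"`.
#' @param multilevel Use study random intercepts for multi-contrast studies.
#' @return A [meta_reml()] fit whose second coefficient is the moderator
#'   slope (change in lnRR per unit dose).
#' @export
meta_regression <- function(effects, moderator = "dose_delta", multilevel = TRUE) {
  stopifnot(is.data.frame(effects))
  if (!moderator %in% names(effects)) {
    stop("moderator column '", moderator, "' not found", call. = FALSE)
  }
  m <- effects[[moderator]]
  if (stats::var(m) == 0) stop("all moderator values identical: no variation", call. = FALSE)
  mods <- matrix(m, ncol = 1, dimnames = list(NULL, moderator))
  meta_reml(effects$lnRR, effects$variance, study = effects$study_id,
            mods = mods, multilevel = multilevel)
}

#' Arm-level (dose, content) points from a study table
#'
#' Flattens a study table into per-arm points for the content-based
#' dose-response fit: one point per unique (study, dose) arm of the chosen
#' outcome, control arms included once even when shared by several
#' contrasts.
#'
#' @param table A [study_table()].
#' @param outcome Outcome to extract (default `"total_gliadin"`).
#' @return data.frame with columns `study_id`, `dose`, `content`.
#' @export
content_dose_points <- function(table, outcome = "total_gliadin") {
  stopifnot(inherits(table, "study_table"))
  tb <- table[table$outcome == outcome, , drop = FALSE]
  if (nrow(tb) == 0L) stop("no records for outcome '", outcome, "'", call. = FALSE)
  pts <- rbind(
    data.frame(study_id = tb$study_id, genotype = tb$genotype,
               dose = tb$dose_control, content = tb$mean_control,
               stringsAsFactors = FALSE),
    data.frame(study_id = tb$study_id, genotype = tb$genotype,
               dose = tb$dose_treatment, content = tb$mean_treatment,
               stringsAsFactors = FALSE))
  pts <- pts[!duplicated(pts[, c("study_id", "genotype", "dose")]), , drop = FALSE]
  rownames(pts) <- NULL
  pts[, c("study_id", "dose", "content")]
}
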