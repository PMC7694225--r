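#' Model-II regression (major axis / standardised major axis / OLS)
#'
#' Slope and intercept of the bivariate relationship when both variables
#' carry error, as used for the country-level association between
#' coeliac-disease prevalence and per-capita wheat intake. Three estimators
#' are computed side by side:
#' \describe{
#'   \item{MA}{major axis: first principal axis of the covariance matrix
#'     (minimises perpendicular residuals);}
#'   \item{SMA}{standardised major axis: `sign(r) * sd_y / sd_x` (minimises
#'     the product of x- and y-residuals);}
#'   \item{OLS}{ordinary least squares, for reference.}
#' }
#' All three lines pass through the centroid. Slope confidence intervals
#' use the classical closed forms: for SMA the `B = t^2 (1 - r^2)/(n - 2)`
#' construction, for MA the eigenvalue-based interval rotated back to slope
#' scale. The p-value is the two-sided Pearson correlation test.
#'
#' @param x,y Numeric vectors (e.g. wheat intake and CD prevalence), at
#'   least 3 points, non-zero variance in both.
#' @param method Primary estimator reported by `coef()`/`print()`:
#'   `"MA"` (default), `"SMA"` or `"OLS"`.
#' @param level Confidence level for the slope intervals.
#' @return Object of class `"model2"`: a `fits` data.frame (one row per
#'   method with slope, intercept, CI bounds), `r`, `r2`, `p_value`, `n`,
#'   the centroid, and the selected `method`.
#' @examples
#' set.seed(7)
#' x <- runif(40, 30, 120); y <- 0.3 + 0.012 * x + rnorm(40, 0, 0.2)
#' model2_fit(x, y)
#' @export
model2_fit <- function(x, y, method = c("MA", "SMA", "OLS"), level = 0.95) {
  method <- match.arg(method)
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  if (length(y) != n) stop("x and y lengths differ", call. = FALSE)
  sxx <- stats::var(x)
  syy <- stats::var(y)
  sxy <- stats::cov(x, y)
  if (sxx == 0 || syy == 0) stop("zero variance in x or y", call. = FALSE)
  r <- sxy / sqrt(sxx * syy)
  ct <- stats::cor.test(x, y)
  xbar <- mean(x)
  ybar <- mean(y)

  # MA slope: larger root of the eigen problem of the covariance matrix
  b_ma <- if (sxy == 0) {
    if (syy > sxx) Inf else 0
  } else {
    (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  }
  if (r == 0 && method == "SMA") {
    stop("r = 0: SMA slope sign undefined", call. = FALSE)
  }
  b_sma <- sign(if (r != 0) r else 1) * sqrt(syy / sxx)
  b_ols <- sxy / sxx

  alpha <- 1 - level
  tcrit <- stats::qt(1 - alpha / 2, n - 2)

  # SMA CI (Jolicoeur & Mosimann construction)
  B <- tcrit^2 * (1 - r^2) / (n - 2)
  ci_sma <- sort(b_sma * c(sqrt(B + 1) + sqrt(B), sqrt(B + 1) - sqrt(B)))

  # MA CI from the eigenvalues, rotated back to slope scale
  lam <- eigen(matrix(c(sxx, sxy, sxy, syy), 2), symmetric = TRUE,
               only.values = TRUE)$values
  H <- stats::qf(level, 1, n - 2) /
    ((lam[1] / lam[2] + lam[2] / lam[1] - 2) * (n - 2))
  if (!is.finite(H) || H >= 1) {
    ci_ma <- c(-Inf, Inf)
  } else {
    A <- sqrt(H / (1 - H))
    lo <- (b_ma - A) / (1 + b_ma * A)
    up <- (b_ma + A) / (1 - b_ma * A)
    ci_ma <- if (1 - b_ma * A <= 0) c(min(lo, up), Inf) else sort(c(lo, up))
  }

  # OLS CI
  se_ols <- sqrt((syy / sxx - b_ols^2) / (n - 2))
  ci_ols <- b_ols + c(-1, 1) * tcrit * se_ols

  slopes <- c(MA = b_ma, SMA = b_sma, OLS = b_ols)
  fits <- data.frame(
    method = c("MA", "SMA", "OLS"),
    slope = unname(slopes),
    intercept = ybar - unname(slopes) * xbar,
    ci_low = c(ci_ma[1], ci_sma[1], ci_ols[1]),
    ci_high = c(ci_ma[2], ci_sma[2], ci_ols[2]),
    stringsAsFactors = FALSE)

  structure(list(fits = fits, method = method, r = r, r2 = r^2,
                 p_value = ct$p.value, n = n,
                 centroid = c(x = xbar, y = ybar), level = level),
            class = "model2")
}

#' @export
coef.model2 <- function(object, method = object$method, ...) {
  row <- object$fits[object$fits$method == method, ]
  c(intercept = row$intercept, slope = row$slope)
}

#' @export
print.model2 <- function(x, digits = 4, ...) {
  cat(sprintf("Model-II regression (n = %d, r = %.*g, p = %.*g)\n",
              x$n, digits, x$r, digits, x$p_value))
  df <- x$fits
  df$primary <- ifelse(df$method == x$method, "*", "")
  print(format(df, digits = digits), row.names = FALSE)
  cat(sprintf("* primary method; %d%% slope CIs\n", round(100 * x$level)))
  invisible(x)
}

#' Correlation between two annual trajectories
#'
#' Pearson correlation of two [time_series()] on their overlapping years
#' (inner join), used to compare the derived per-capita gliadin-intake
#' trajectory with coeliac-disease prevalence/incidence series. Because
#' "increase correlated with increase" can be read on levels or on changes,
#' `diff = TRUE` correlates year-on-year first differences instead of raw
#' values.
#'
#' @param a,b Two `time_series` with at least 3 overlapping years
#'   (4 when `diff = TRUE`).
#' @param diff Correlate first differences instead of levels.
#' @return List with `r`, `p_value`, `n_overlap` (and `diff`).
#' @export
trajectory_correlation <- function(a, b, diff = FALSE) {
  stopifnot(inherits(a, "time_series"), inherits(b, "time_series"))
  common <- intersect(a$year, b$year)
  va <- a$value[match(common, a$year)]
  vb <- b$value[match(common, b$year)]
  if (diff) {
    # differencing is only meaningful on consecutive years
    keep <- which(base::diff(common) == 1L)
    va <- base::diff(va)[keep]
    vb <- base::diff(vb)[keep]
  }
  if (length(va) < 3L) stop("need at least 3 overlapping years", call. = FALSE)
  ct <- stats::cor.test(va, vb)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       n_overlap = length(common), diff = diff)
}

#' Read a country panel (intake vs prevalence) from CSV
#'
#' Expects columns `country_code,wheat_intake_kg,cd_prevalence_pct`.
#'
#' @param path CSV path.
#' @return data.frame of class `"country_panel"`.
#' @export
read_country_panel <- function(path) {
  if (!file.exists(path)) stop("country panel file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("country_code", "wheat_intake_kg", "cd_prevalence_pct")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("country panel schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(df$cd_prevalence_pct < 0 | df$cd_prevalence_pct > 100)) {
    stop("prevalence must lie in [0, 100] %", call. = FALSE)
  }
  if (any(df$wheat_intake_kg < 0)) stop("intake must be non-negative", call. = FALSE)
  class(df) <- c("country_panel", "data.frame")
  df
}

#' @rdname read_country_panel
#' @param x A `country_panel`.
#' @return `write_country_panel()`: invisibly, `path`.
#' @export
write_country_panel <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
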