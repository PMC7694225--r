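# Restricted log-likelihood of the (multilevel) random-effects model.
#
# Marginal model: y ~ N(X beta, V),  V = diag(v + tau2) + sigma2 * Z Z'
# where Z groups effects by study. V is block-diagonal by study, so each
# block inverse/determinant comes from one rank-1 (Sherman-Morrison) update;
# everything is O(k) per evaluation.
reml_loglik <- function(tau2, sigma2, yi, vi, X, study) {
  k <- length(yi)
  p <- ncol(X)
  d <- vi + tau2
  if (any(d <= 0)) return(-Inf)

  XtVX <- matrix(0, p, p)
  XtVy <- numeric(p)
  yVy <- 0
  logdetV <- 0
  if (sigma2 > 0 && !is.null(study)) {
    for (idx in split(seq_len(k), study)) {
      db <- d[idx]
      yb <- yi[idx]
      Xb <- X[idx, , drop = FALSE]
      cb <- sum(1 / db)
      shrink <- sigma2 / (1 + sigma2 * cb)
      # M^-1 x = x/d - shrink * (sum(x/d)) * (1/d)
      yd <- yb / db
      Xd <- Xb / db
      XtVX <- XtVX + crossprod(Xb, Xd) - shrink * tcrossprod(colSums(Xd))
      XtVy <- XtVy + crossprod(Xd, yb) - shrink * colSums(Xd) * sum(yd)
      yVy <- yVy + sum(yb * yd) - shrink * sum(yd)^2
      logdetV <- logdetV + sum(log(db)) + log1p(sigma2 * cb)
    }
  } else {
    yd <- yi / d
    Xd <- X / d
    XtVX <- crossprod(X, Xd)
    XtVy <- drop(crossprod(Xd, yi))
    yVy <- sum(yi * yd)
    logdetV <- sum(log(d))
  }

  chXtVX <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(chXtVX)) return(-Inf)
  beta <- backsolve(chXtVX, forwardsolve(t(chXtVX), XtVy))
  quad <- yVy - sum(beta * XtVy)
  ll <- -0.5 * ((k - p) * log(2 * pi) + logdetV +
                  2 * sum(log(diag(chXtVX))) + quad)
  attr(ll, "beta") <- beta
  attr(ll, "XtVX_chol") <- chXtVX
  ll
}

# DerSimonian-Laird moment estimate of total heterogeneity; used as the
# starting point for the likelihood search.
tau2_dl <- function(yi, vi) {
  w <- 1 / vi
  yw <- sum(w * yi) / sum(w)
  Q <- sum(w * (yi - yw)^2)
  k <- length(yi)
  max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
}

#' Random-effects meta-analysis by restricted maximum likelihood
#'
#' Pools log response ratios (or any effect sizes with known sampling
#' variances) under the random-effects model
#' \deqn{y_j \sim N(\mu + x_j'\beta,\; v_j + \tau^2),}
#' estimating the between-effect heterogeneity \eqn{\tau^2} by REML. When a
#' `study` grouping is supplied and any study contributes more than one
#' contrast, a study-level random intercept with variance
#' \eqn{\sigma^2_{study}} is added on top of the residual \eqn{\tau^2}
#' (two-level model); with one effect per study this collapses to the
#' standard random-effects model. The 95% confidence interval uses the
#' normal quantile, and an effect is flagged significant when the interval
#' excludes zero.
#'
#' @param yi Numeric vector of effect sizes (e.g. lnRR).
#' @param vi Sampling variances, all `> 0`.
#' @param study Optional grouping factor/labels for the study-level random
#'   intercept.
#' @param mods Optional numeric moderator vector or matrix (meta-regression);
#'   an intercept is always included.
#' @param multilevel If `FALSE`, ignore `study` and fit the single
#'   heterogeneity component even when studies repeat.
#' @param level Confidence level (default 0.95).
#' @param tau2_max Upper bound of the heterogeneity search; defaults to
#'   `10 * var(yi)` (floored at 1e-3 for degenerate inputs).
#' @param reltol Convergence tolerance of the likelihood search.
#' @return Object of class `"meta_reml"` with coefficients, their standard
#'   errors and Wald statistics, `tau2`, `sigma2_study` (`NA` for
#'   single-level fits), the CI bounds and the significance flag. Methods:
#'   `print`, `summary`, `coef`, `confint`, `logLik`.
#' @examples
#' set.seed(1)
#' fit <- meta_reml(rnorm(12, 0.3, 0.1), rep(0.01, 12))
#' coef(fit); confint(fit)
#' @export
meta_reml <- function(yi, vi, study = NULL, mods = NULL, multilevel = TRUE,
                      level = 0.95, tau2_max = NULL, reltol = 1e-8) {
  yi <- as.numeric(yi)
  vi <- as.numeric(vi)
  k <- length(yi)
  if (k < 2L) stop("need at least two effects to pool", call. = FALSE)
  if (length(vi) != k) stop("yi and vi lengths differ", call. = FALSE)
  if (any(!is.finite(yi)) || any(!is.finite(vi)) || any(vi <= 0)) {
    stop("effects must be finite with strictly positive sampling variances",
         call. = FALSE)
  }

  X <- cbind(intercept = rep(1, k))
  if (!is.null(mods)) {
    mods <- as.matrix(mods)
    if (nrow(mods) != k) stop("moderator rows must match effects", call. = FALSE)
    if (is.null(colnames(mods))) colnames(mods) <- paste0("mod", seq_len(ncol(mods)))
    X <- cbind(X, mods)
  }
  p <- ncol(X)
  if (k <= p) stop("more coefficients than effects", call. = FALSE)

  use_study <- multilevel && !is.null(study) && anyDuplicated(study) > 0L
  study_f <- if (!is.null(study)) factor(study) else NULL
  if (is.null(tau2_max)) tau2_max <- max(10 * stats::var(yi), 1e-3)

  if (!use_study) {
    opt <- stats::optimize(function(t2) as.numeric(reml_loglik(t2, 0, yi, vi, X, NULL)),
                           interval = c(0, tau2_max), maximum = TRUE, tol = reltol)
    tau2 <- opt$maximum
    # optimize() never evaluates the boundary itself; snap to 0 if better
    if (as.numeric(reml_loglik(0, 0, yi, vi, X, NULL)) >= opt$objective) tau2 <- 0
    sigma2 <- 0
    ll <- reml_loglik(tau2, sigma2, yi, vi, X, NULL)
  } else {
    start <- rep(max(tau2_dl(yi, vi) / 2, 1e-6), 2)
    negll <- function(th) -as.numeric(reml_loglik(th[1], th[2], yi, vi, X, study_f))
    opt <- stats::nlminb(start, negll, lower = c(0, 0), upper = rep(tau2_max, 2),
                         control = list(iter.max = 200, eval.max = 500,
                                        rel.tol = reltol))
    if (!opt$convergence %in% c(0, 1)) {
      stop("REML did not converge within the iteration cap (last iterate tau2=",
           signif(opt$par[1], 6), ", sigma2_study=", signif(opt$par[2], 6), ")",
           call. = FALSE)
    }
    tau2 <- opt$par[1]
    sigma2 <- opt$par[2]
    ll <- reml_loglik(tau2, sigma2, yi, vi, X, study_f)
  }

  beta <- attr(ll, "beta")
  chXtVX <- attr(ll, "XtVX_chol")
  vcov_b <- chol2inv(chXtVX)
  se <- sqrt(diag(vcov_b))
  names(beta) <- names(se) <- colnames(X)
  dimnames(vcov_b) <- list(colnames(X), colnames(X))
  zcrit <- stats::qnorm(1 - (1 - level) / 2)
  ci_low <- beta - zcrit * se
  ci_high <- beta + zcrit * se
  zval <- beta / se
  pval <- 2 * stats::pnorm(-abs(zval))

  structure(list(
    beta = beta, se = se, vcov = vcov_b, zval = zval, pval = pval,
    ci_low = ci_low, ci_high = ci_high, level = level,
    tau2 = tau2, sigma2_study = if (use_study) sigma2 else NA_real_,
    multilevel = use_study, k = k, p = p,
    n_studies = if (!is.null(study_f)) nlevels(study_f) else k,
    logLik = as.numeric(ll), yi = yi, vi = vi, X = X, study = study_f,
    significant = unname(ci_low[1] > 0 || ci_high[1] < 0)),
    class = "meta_reml")
}

#' Is a pooled effect significant by CI overlap?
#'
#' An effect is declared significant when its 95% (or `level`) confidence
#' interval does not overlap zero — the decision rule used for the forest
#' summary. Works on a single fit or on a whole forest summary table.
#'
#' @param x A `meta_reml` fit or a `forest_summary` data.frame.
#' @return Logical scalar (fit) or vector (summary table).
#' @export
significance_flag <- function(x) {
  if (inherits(x, "meta_reml")) {
    return(unname(x$ci_low[1] > 0 || x$ci_high[1] < 0))
  }
  if (is.data.frame(x) && all(c("ci_low", "ci_high") %in% names(x))) {
    return(x$ci_low > 0 | x$ci_high < 0)
  }
  stop("significance_flag expects a meta_reml fit or a forest summary", call. = FALSE)
}

#' Per-outcome pooled effects (forest summary)
#'
#' Fits one random-effects model per outcome group and returns the pooled
#' log response ratio, its confidence interval, heterogeneity and the
#' CI-overlap significance flag, in the fixed reporting order
#' gluten, total gliadin, alpha/beta-, gamma-, omega-gliadin, transcripts.
#'
#' @param effects An [effect_sizes()] data.frame (post-filtering).
#' @param multilevel Passed to [meta_reml()]; study random intercepts are
#'   used where studies contribute several contrasts.
#' @param level Confidence level.
#' @return data.frame of class `"forest_summary"` with one row per outcome:
#'   `outcome, k, n_studies, mu_hat, se, ci_low, ci_high, tau2,
#'   sigma2_study, p_value, significant`.
#' @export
forest_summary <- function(effects, multilevel = TRUE, level = 0.95) {
  stopifnot(inherits(effects, "data.frame"))
  if (nrow(effects) == 0L) stop("no effect sizes to summarise", call. = FALSE)
  groups <- intersect(outcome_levels(), unique(effects$outcome))
  rows <- lapply(groups, function(oc) {
    e <- effects[effects$outcome == oc, , drop = FALSE]
    fit <- meta_reml(e$lnRR, e$variance, study = e$study_id,
                     multilevel = multilevel, level = level)
    data.frame(outcome = oc, k = fit$k, n_studies = fit$n_studies,
               mu_hat = unname(fit$beta[1]), se = unname(fit$se[1]),
               ci_low = unname(fit$ci_low[1]), ci_high = unname(fit$ci_high[1]),
               tau2 = fit$tau2, sigma2_study = fit$sigma2_study,
               p_value = unname(fit$pval[1]), significant = fit$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("forest_summary", "data.frame")
  out
}

#' @export
print.meta_reml <- function(x, digits = 4, ...) {
  cat("Random-effects meta-analysis (REML)\n")
  cat(sprintf("  k = %d effects, %d studies%s\n", x$k, x$n_studies,
              if (x$multilevel) " (study random intercept)" else ""))
  cat(sprintf("  tau^2 = %.*g", digits, x$tau2))
  if (x$multilevel) cat(sprintf(", sigma^2_study = %.*g", digits, x$sigma2_study))
  cat("\n")
  est <- cbind(estimate = x$beta, se = x$se, z = x$zval, p = x$pval,
               ci.lb = x$ci_low, ci.ub = x$ci_high)
  print(round(est, digits))
  if (x$p == 1L) {
    cat(if (x$significant) "Pooled effect significant" else "Pooled effect not significant",
        sprintf("(%d%% CI %s zero)\n", round(100 * x$level),
                if (x$significant) "excludes" else "overlaps"))
  }
  invisible(x)
}

#' @export
summary.meta_reml <- function(object, ...) object

#' @export
coef.meta_reml <- function(object, ...) object$beta

#' @export
vcov.meta_reml <- function(object, ...) object$vcov

#' @export
confint.meta_reml <- function(object, parm, level, ...) {
  ci <- cbind(object$ci_low, object$ci_high)
  colnames(ci) <- paste0(round(100 * c((1 - object$level) / 2,
                                       1 - (1 - object$level) / 2), 1), " %")
  ci
}

#' @export
logLik.meta_reml <- function(object, ...) {
  structure(object$logLik, df = object$p + 1L + object$multilevel,
            class = "logLik")
}

#' @export
print.forest_summary <- function(x, digits = 3, ...) {
  cat("Pooled response ratios by outcome (REML random effects)\n")
  df <- as.data.frame(x)
  df$`lnRR [95% CI]` <- sprintf("%+.*f [%+.*f, %+.*f]%s", digits, df$mu_hat,
                                digits, df$ci_low, digits, df$ci_high,
                                ifelse(df$significant, " *", ""))
  print(df[, c("outcome", "k", "n_studies", "lnRR [95% CI]", "tau2")],
        row.names = FALSE)
  cat("* 95% CI excludes zero\n")
  invisible(x)
}
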