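#' Natural-log response ratio
#'
#' The effect size used throughout the pipeline: `ln(X_t / X_c)`, the log
#' ratio of the treatment-arm mean to the control-arm mean. It is
#' dimensionless, antisymmetric under swapping the arms and invariant to a
#' common rescaling of both means, which is what lets concentrations
#' reported in different units be pooled.
#'
#' @param mean_treatment,mean_control Positive arm means (vectorised).
#' @return `log(mean_treatment) - log(mean_control)`.
#' @export
ln_response_ratio <- function(mean_treatment, mean_control) {
  if (any(!is.finite(mean_treatment)) || any(!is.finite(mean_control)) ||
      any(mean_treatment <= 0) || any(mean_control <= 0)) {
    stop("ln response ratio requires positive, finite arm means", call. = FALSE)
  }
  log(mean_treatment) - log(mean_control)
}

#' Sampling variance of the log response ratio
#'
#' Large-sample (delta-method) variance of `ln(X_t/X_c)` from the per-arm
#' summary statistics:
#' `v = S_t^2 / (n_t X_t^2) + S_c^2 / (n_c X_c^2)`.
#' Both SDs zero gives a degenerate zero-variance effect that cannot be
#' inverse-variance weighted and is rejected.
#'
#' @param mean_treatment,sd_treatment,n_treatment Treatment-arm mean, SD and
#'   sample size.
#' @param mean_control,sd_control,n_control Control-arm mean, SD and sample
#'   size.
#' @return Sampling variance, strictly positive (vectorised).
#' @export
sampling_variance <- function(mean_treatment, sd_treatment, n_treatment,
                              mean_control, sd_control, n_control) {
  if (any(n_treatment < 2) || any(n_control < 2)) {
    stop("sampling variance requires at least 2 replicates per arm", call. = FALSE)
  }
  if (any(mean_treatment <= 0) || any(mean_control <= 0)) {
    stop("sampling variance requires positive arm means", call. = FALSE)
  }
  if (any(sd_treatment < 0) || any(sd_control < 0)) {
    stop("negative standard deviation", call. = FALSE)
  }
  v <- sd_treatment^2 / (n_treatment * mean_treatment^2) +
    sd_control^2 / (n_control * mean_control^2)
  if (any(v <= 0)) {
    stop("zero sampling variance (both arm SDs are zero); effect cannot be weighted",
         call. = FALSE)
  }
  v
}

#' Compute effect sizes from a study table, filtering sparse outcomes
#'
#' Turns every contrast in a [study_table()] into a log response ratio with
#' its sampling variance, then drops outcome groups that do not exceed
#' `min_obs` observations (the default keeps only outcomes with more than 30
#' effects, the global-evidence threshold used for the pooled analysis).
#' Dropped groups are reported via `message()`.
#'
#' @param table A `study_table`.
#' @param min_obs Retain an outcome only if it has strictly more than this
#'   many effects. Default 30.
#' @return data.frame of class `"effect_sizes"` with columns `study_id`,
#'   `outcome`, `dose_control`, `dose_treatment`, `dose_delta`, `lnRR`,
#'   `variance`. May have zero rows (with a warning) if every group is
#'   below threshold.
#' @export
effect_sizes <- function(table, min_obs = 30) {
  stopifnot(inherits(table, "study_table"))
  if (nrow(table) == 0L) stop("empty study table", call. = FALSE)
  if (min_obs < 1) stop("min_obs must be >= 1", call. = FALSE)

  es <- data.frame(
    study_id = table$study_id,
    outcome = table$outcome,
    dose_control = table$dose_control,
    dose_treatment = table$dose_treatment,
    dose_delta = table$dose_treatment - table$dose_control,
    lnRR = ln_response_ratio(table$mean_treatment, table$mean_control),
    variance = sampling_variance(table$mean_treatment, table$sd_treatment,
                                 table$n_treatment, table$mean_control,
                                 table$sd_control, table$n_control),
    stringsAsFactors = FALSE)

  counts <- table(es$outcome)
  drop <- names(counts)[counts <= min_obs]
  if (length(drop)) {
    message("dropping outcome group(s) with <= ", min_obs, " observations: ",
            paste(sprintf("%s (k=%d)", drop, counts[drop]), collapse = ", "))
    es <- es[!(es$outcome %in% drop), , drop = FALSE]
  }
  if (nrow(es) == 0L) {
    warning("no outcome group exceeds the ", min_obs, "-observation threshold",
            call. = FALSE)
  }
  rownames(es) <- NULL
  class(es) <- c("effect_sizes", "data.frame")
  es
}

#' Write effect sizes to CSV
#'
#' @param x An `effect_sizes` data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_effect_sizes <- function(x, path) {
  stopifnot(inherits(x, "effect_sizes"))
  cols <- c("study_id", "outcome", "dose_control", "dose_treatment", "lnRR", "variance")
  utils::write.csv(as.data.frame(x)[, cols], path, row.names = FALSE)
  invisible(path)
}
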