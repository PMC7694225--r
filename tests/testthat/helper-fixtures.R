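# Small in-code fixtures shared across test files.

# one valid study-table row, overridable field by field
stub_row <- function(...) {
  row <- list(study_id = "S01", outcome = "total_gliadin",
              dose_control = 0, dose_treatment = 120,
              mean_control = 44, sd_control = 4.4, n_control = 4,
              mean_treatment = 52, sd_treatment = 5.2, n_treatment = 4,
              genotype = "Soissons")
  mods <- list(...)
  row[names(mods)] <- mods
  as.data.frame(row, stringsAsFactors = FALSE)
}

# independent brute-force oracle for single-level REML: profile restricted
# log-likelihood maximised over a dense tau^2 grid (intercept-only model)
grid_reml_tau2 <- function(yi, vi, grid = seq(0, 2, by = 1e-4)) {
  k <- length(yi)
  ll <- vapply(grid, function(t2) {
    w <- 1 / (vi + t2)
    mu <- sum(w * yi) / sum(w)
    -0.5 * (sum(log(vi + t2)) + log(sum(w)) + sum(w * (yi - mu)^2))
  }, numeric(1))
  grid[which.max(ll)]
}

# random small meta-analytic instances for oracle comparisons
random_meta_instance <- function(k = 8) {
  vi <- runif(k, 0.005, 0.08)
  tau2 <- runif(1, 0, 0.3)
  yi <- rnorm(k, 0.2, sqrt(vi + tau2))
  list(yi = yi, vi = vi)
}
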