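#' Outcome categories handled by the pipeline
#'
#' The six grain/flour outcomes pooled in the meta-analysis, in their fixed
#' reporting order: total gluten, total gliadins, the three gliadin families
#' (alpha/beta, gamma, omega) and gliadin transcript abundance.
#'
#' @return Character vector of the six outcome codes.
#' @export
outcome_levels <- function() {
  c("total_gluten", "total_gliadin", "ab_gliadin",
    "g_gliadin", "w_gliadin", "gliadin_transcript")
}

# bit-exact CSV header for study-extraction tables
STUDY_TABLE_COLUMNS <- c(
  "study_id", "outcome", "dose_control", "dose_treatment",
  "mean_control", "sd_control", "n_control",
  "mean_treatment", "sd_treatment", "n_treatment", "genotype"
)

#' Construct a validated study-extraction table
#'
#' A study table holds one row per control/treatment contrast extracted from
#' a fertilisation experiment: arm means, SDs and sample sizes of a grain or
#' flour outcome at two nitrogen doses. All rows are validated against the
#' invariants the log response-ratio machinery requires (positive means,
#' non-negative SDs, at least two replicates per arm, treatment dose above
#' control dose) and the (study, outcome, dose pair) triple must be unique.
#'
#' @param records data.frame with the columns listed under
#'   [read_study_table()]. `genotype` may be omitted (filled with `""`).
#' @return The validated data.frame with class `"study_table"`.
#' @seealso [read_study_table()], [contrasts_from_dose_series()]
#' @export
study_table <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (is.null(records$genotype)) records$genotype <- ""
  validate_study_table(records)
  records <- records[, STUDY_TABLE_COLUMNS]
  class(records) <- c("study_table", "data.frame")
  records
}

#' Validate a study table against its invariants
#'
#' @param df data.frame candidate.
#' @return Invisibly `TRUE`; otherwise an error naming the offending column
#'   or row.
#' @export
validate_study_table <- function(df) {
  missing_cols <- setdiff(STUDY_TABLE_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("study table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) < 1L) stop("study table must contain at least one record", call. = FALSE)

  num_cols <- c("dose_control", "dose_treatment", "mean_control", "sd_control",
                "n_control", "mean_treatment", "sd_treatment", "n_treatment")
  for (cl in num_cols) {
    if (!is.numeric(df[[cl]])) {
      stop("study table schema error: column '", cl, "' must be numeric", call. = FALSE)
    }
    bad <- which(!is.finite(df[[cl]]))
    if (length(bad)) {
      stop("study table validation error: non-finite '", cl, "' in row ", bad[1L],
           call. = FALSE)
    }
  }

  fail_row <- function(cond, msg) {
    bad <- which(cond)
    if (length(bad)) {
      stop("study table validation error: ", msg, " in row ", bad[1L], call. = FALSE)
    }
  }
  fail_row(df$mean_control <= 0, "non-positive mean_control (log ratio undefined)")
  fail_row(df$mean_treatment <= 0, "non-positive mean_treatment (log ratio undefined)")
  fail_row(df$sd_control < 0, "negative sd_control")
  fail_row(df$sd_treatment < 0, "negative sd_treatment")
  fail_row(df$n_control < 2, "n_control < 2")
  fail_row(df$n_treatment < 2, "n_treatment < 2")
  fail_row(df$dose_treatment <= df$dose_control, "dose_treatment <= dose_control")
  fail_row(!(df$outcome %in% outcome_levels()),
           paste0("unknown outcome (expected one of ",
                  paste(outcome_levels(), collapse = ", "), ")"))

  key <- paste(df$study_id, df$outcome, df$dose_control, df$dose_treatment, df$genotype,
               sep = "\r")
  fail_row(duplicated(key), "duplicate (study_id, outcome, dose pair, genotype) triple")
  invisible(TRUE)
}

#' Read a study-extraction table from CSV
#'
#' Expects the exact header
#' `study_id,outcome,dose_control,dose_treatment,mean_control,sd_control,n_control,mean_treatment,sd_treatment,n_treatment,genotype`
#' (comma-separated, UTF-8, `.` decimal separator). Row order is preserved
#' and every row is validated; the source path and its MD5 checksum are kept
#' as provenance attributes.
#'
#' @param path Path to the CSV file.
#' @return A [study_table()] with attributes `source` and `checksum`.
#' @export
read_study_table <- function(path) {
  if (!file.exists(path)) stop("study table file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(study_id = "character",
                                       outcome = "character",
                                       genotype = "character"))
  tab <- study_table(df)
  attr(tab, "source") <- path
  attr(tab, "checksum") <- unname(tools::md5sum(path))
  tab
}

#' Write a study table to CSV
#'
#' Inverse of [read_study_table()]: writes the documented header and one row
#' per contrast, so that read(write(x)) round-trips exactly.
#'
#' @param x A `study_table`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_study_table <- function(x, path) {
  stopifnot(inherits(x, "study_table"))
  utils::write.csv(as.data.frame(x)[, STUDY_TABLE_COLUMNS], path,
                   row.names = FALSE, quote = which(STUDY_TABLE_COLUMNS %in%
                                                      c("study_id", "outcome", "genotype")))
  invisible(path)
}

#' Expand a multi-dose series into control/treatment contrasts
#'
#' Fertilisation experiments typically report one arm per dose level
#' (e.g. 0, 120, 240, 360 kg N ha^-1 y^-1). Under the default `"lowest"`
#' pairing every higher dose is contrasted against the lowest dose as the
#' common control, the standard convention in fertilisation meta-analyses;
#' `"adjacent"` pairs each dose against the next lower one instead. Either
#' way, `k` dose levels yield `k - 1` contrasts.
#'
#' @param study_id Study label.
#' @param outcome One of [outcome_levels()].
#' @param dose Numeric vector of dose levels, sorted ascending, no duplicates.
#' @param mean,sd,n Numeric vectors parallel to `dose`: per-arm mean,
#'   standard deviation and replicate count.
#' @param genotype Free-text genotype label (recycled).
#' @param pairing `"lowest"` (default) or `"adjacent"`.
#' @return A [study_table()] with `length(dose) - 1` rows.
#' @examples
#' contrasts_from_dose_series("S1", "total_gluten",
#'   dose = c(0, 120, 240, 360),
#'   mean = c(40, 45, 50, 55), sd = rep(4, 4), n = rep(4, 4))
#' @export
contrasts_from_dose_series <- function(study_id, outcome, dose, mean, sd, n,
                                       genotype = "",
                                       pairing = c("lowest", "adjacent")) {
  pairing <- match.arg(pairing)
  k <- length(dose)
  if (k < 2L) stop("need at least two dose levels", call. = FALSE)
  if (anyDuplicated(dose)) stop("duplicate dose levels", call. = FALSE)
  if (is.unsorted(dose, strictly = TRUE)) stop("dose levels must be sorted ascending", call. = FALSE)
  stopifnot(length(mean) == k, length(sd) == k, length(n) == k)

  ctrl <- if (pairing == "lowest") rep(1L, k - 1L) else seq_len(k - 1L)
  trt <- 2:k
  study_table(data.frame(
    study_id = study_id, outcome = outcome,
    dose_control = dose[ctrl], dose_treatment = dose[trt],
    mean_control = mean[ctrl], sd_control = sd[ctrl], n_control = n[ctrl],
    mean_treatment = mean[trt], sd_treatment = sd[trt], n_treatment = n[trt],
    genotype = genotype, stringsAsFactors = FALSE))
}

#' @export
print.study_table <- function(x, ...) {
  cat("Study-extraction table: ", nrow(x), " contrast(s), ",
      length(unique(x$study_id)), " study(ies), ",
      length(unique(x$outcome)), " outcome(s)\n", sep = "")
  NextMethod()
}
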