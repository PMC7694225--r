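# units recognised on annual series flowing through the intake chain
TS_UNITS <- c("kg N ha-1 y-1", "kg y-1 per capita", "mg g-1", "%")

#' Construct an annual time series
#'
#' A thin container for the annual series the intake derivation works on:
#' strictly increasing integer years, finite values and a declared unit
#' (one of `kg N ha-1 y-1`, `kg y-1 per capita`, `mg g-1`, `%`). Missing
#' interior years can be filled by linear interpolation with
#' [fill_year_gaps()].
#'
#' @param years Integer years, strictly increasing.
#' @param values Finite numeric values, same length.
#' @param unit Unit string.
#' @return data.frame of class `"time_series"` with columns `year`, `value`
#'   and a `unit` attribute.
#' @export
time_series <- function(years, values, unit) {
  years <- as.integer(years)
  values <- as.numeric(values)
  if (length(years) != length(values)) stop("years and values lengths differ", call. = FALSE)
  if (length(years) == 0L) stop("empty time series", call. = FALSE)
  if (is.unsorted(years, strictly = TRUE)) {
    stop("years must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("time-series values must be finite", call. = FALSE)
  if (!is.character(unit) || length(unit) != 1L || !unit %in% TS_UNITS) {
    stop("unit must be one of: ", paste(TS_UNITS, collapse = ", "), call. = FALSE)
  }
  structure(data.frame(year = years, value = values),
            unit = unit, class = c("time_series", "data.frame"))
}

#' @rdname time_series
#' @param x A `time_series`.
#' @return `ts_unit()`: the unit string.
#' @export
ts_unit <- function(x) attr(x, "unit")

#' Fill interior year gaps by linear interpolation
#'
#' Missing years strictly inside the observed range are filled with
#' linearly interpolated values and recorded in the `interpolated`
#' attribute; no extrapolation beyond the observed endpoints is performed.
#'
#' @param x A [time_series()].
#' @return A complete-year `time_series`; `attr(, "interpolated")` lists the
#'   filled years (integer(0) when none).
#' @export
fill_year_gaps <- function(x) {
  stopifnot(inherits(x, "time_series"))
  full <- seq(min(x$year), max(x$year))
  missing_years <- setdiff(full, x$year)
  if (length(missing_years) == 0L) {
    attr(x, "interpolated") <- integer(0)
    return(x)
  }
  vals <- stats::approx(x$year, x$value, xout = full, method = "linear")$y
  out <- time_series(full, vals, ts_unit(x))
  attr(out, "interpolated") <- as.integer(missing_years)
  out
}

#' Read an annual series from CSV
#'
#' Expects columns `year,value`. The unit is taken from `unit`, or, when
#' `NULL`, from a YAML sidecar `<path>.yml` containing a `unit:` field.
#'
#' @param path CSV path.
#' @param unit Unit string, or `NULL` to read the sidecar.
#' @return A [time_series()].
#' @export
read_time_series <- function(path, unit = NULL) {
  if (!file.exists(path)) stop("time-series file not found: ", path, call. = FALSE)
  if (is.null(unit)) {
    sidecar <- paste0(path, ".yml")
    if (!file.exists(sidecar)) {
      stop("no unit given and no sidecar ", sidecar, " found", call. = FALSE)
    }
    unit <- yaml::read_yaml(sidecar)$unit
  }
  df <- utils::read.csv(path)
  if (!all(c("year", "value") %in% names(df))) {
    stop("time-series CSV must have columns year,value", call. = FALSE)
  }
  time_series(df$year, df$value, unit)
}

#' Write an annual series to CSV (with unit sidecar)
#'
#' @param x A `time_series`.
#' @param path Output CSV path; a YAML sidecar `<path>.yml` records the unit.
#' @return Invisibly, `path`.
#' @export
write_time_series <- function(x, path) {
  stopifnot(inherits(x, "time_series"))
  utils::write.csv(data.frame(year = x$year, value = x$value), path, row.names = FALSE)
  yaml::write_yaml(list(unit = ts_unit(x)), paste0(path, ".yml"))
  invisible(path)
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("Annual series [%s]: %d-%d (%d years)\n", ts_unit(x),
              min(x$year), max(x$year), nrow(x)))
  NextMethod()
}
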