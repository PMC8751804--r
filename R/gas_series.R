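#' Construct a shift-level gas concentration time series
#'
#' A `gas_series` holds one work shift's direct-reading sensor log: strictly
#' increasing timestamps on a (near-)regular grid and one non-negative
#' concentration reading (ppm) per timestamp. All downstream operations
#' (moving averages, task segmentation, the exposure index) assume this
#' regular-interval contract, so construction validates it.
#'
#' @param timestamps `POSIXct` vector (or something coercible via
#'   [as.POSIXct()]), strictly increasing.
#' @param readings numeric vector of concentrations in ppm, same length as
#'   `timestamps`, finite and `>= 0`.
#' @param interval logging interval in seconds. Default `NULL` infers it as
#'   the median of consecutive timestamp differences.
#' @param meta named list of free-form provenance (source file, instrument
#'   label, gap-fill flags).
#' @param tolerance allowed relative deviation of each consecutive timestamp
#'   difference from `interval` (default 0.05, i.e. +/-5%).
#' @return An object of class `gas_series`: a list with fields `timestamps`,
#'   `readings`, `interval` (seconds) and `meta`.
#' @seealso [read_series()], [validate_series()], [fill_short_gaps()]
#' @examples
#' ts <- as.POSIXct("2014-03-10 07:00:00", tz = "UTC") + seq(0, 90, by = 10)
#' gs <- gas_series(ts, c(0, 0, 0.4, 1.2, 6.0, 2.1, 0.3, 0, 0, 0))
#' gs
#' @export
gas_series <- function(timestamps, readings, interval = NULL, meta = list(),
                       tolerance = 0.05) {
  if (!inherits(timestamps, "POSIXct")) {
    timestamps <- as.POSIXct(timestamps, tz = "UTC")
  }
  if (is.null(interval)) interval <- infer_interval(timestamps)
  x <- new_gas_series(timestamps, readings, interval, meta)
  validate_series(x, tolerance = tolerance)
}

# Unvalidated constructor; used internally where validation is deferred
# (e.g. between reading a file with dropped samples and gap filling).
new_gas_series <- function(timestamps, readings, interval, meta = list()) {
  structure(
    list(
      timestamps = timestamps,
      readings = as.numeric(readings),
      interval = as.numeric(interval),
      meta = meta
    ),
    class = "gas_series"
  )
}

infer_interval <- function(timestamps) {
  d <- as.numeric(diff(timestamps), units = "secs")
  if (length(d) == 0) h2s_error("need at least 2 samples to infer a logging interval",
                                "h2s_parse_error")
  stats::median(d)
}

#' Validate the regular-interval contract of a gas series
#'
#' Checks every invariant the analysis pipeline relies on: length >= 2,
#' strictly increasing timestamps, finite non-negative readings, and all
#' consecutive timestamp differences within `tolerance` of the logging
#' interval. Violations raise classed conditions (`h2s_parse_error`,
#' `h2s_interval_error`, `h2s_negative_error`) so callers can distinguish
#' malformed files from irregular grids from sensor-drift negatives.
#'
#' @param series a `gas_series` (possibly built without validation).
#' @param tolerance relative deviation allowed per interval (default 0.05).
#' @return `series`, invisibly, if valid.
#' @export
validate_series <- function(series, tolerance = 0.05) {
  stopifnot(inherits(series, "gas_series"))
  n <- length(series$readings)
  if (length(series$timestamps) != n) {
    h2s_error("timestamps and readings differ in length", "h2s_parse_error")
  }
  if (n < 2) h2s_error("a gas series needs at least 2 samples", "h2s_parse_error")
  if (anyNA(series$timestamps)) {
    h2s_error(sprintf("unparseable timestamp at row(s) %s",
                      paste(which(is.na(series$timestamps)), collapse = ", ")),
              "h2s_parse_error")
  }
  if (!all(is.finite(series$readings))) {
    h2s_error(sprintf("non-finite reading at row(s) %s",
                      paste(utils::head(which(!is.finite(series$readings)), 5),
                            collapse = ", ")),
              "h2s_parse_error")
  }
  if (any(series$readings < 0)) {
    bad <- which(series$readings < 0)
    h2s_error(sprintf(
      "negative reading(s) at row(s) %s (sensor drift must be corrected upstream, not clipped)",
      paste(utils::head(bad, 5), collapse = ", ")), "h2s_negative_error")
  }
  d <- as.numeric(diff(series$timestamps), units = "secs")
  if (any(d <= 0)) {
    h2s_error(sprintf("timestamps not strictly increasing at row(s) %s",
                      paste(utils::head(which(d <= 0) + 1, 5), collapse = ", ")),
              "h2s_parse_error")
  }
  iv <- series$interval
  off <- abs(d - iv) > tolerance * iv
  if (any(off)) {
    gaps <- which(off)
    h2s_error(sprintf(
      "irregular logging interval: expected %.3g s (+/-%g%%) but found gap(s) of %s s after row(s) %s",
      iv, 100 * tolerance,
      paste(utils::head(signif(d[gaps], 4), 5), collapse = ", "),
      paste(utils::head(gaps, 5), collapse = ", ")), "h2s_interval_error")
  }
  invisible(series)
}

#' @export
print.gas_series <- function(x, ...) {
  n <- length(x$readings)
  cat(sprintf("<gas_series> %d samples @ %g s (%.2f h)\n", n, x$interval,
              n * x$interval / 3600))
  cat(sprintf("  %s .. %s\n", format(x$timestamps[1]), format(x$timestamps[n])))
  cat(sprintf("  readings: max %.3g ppm, %d positive (%.1f%%)\n",
              max(x$readings), sum(x$readings > 0),
              100 * mean(x$readings > 0)))
  if (!is.null(x$meta$source)) cat(sprintf("  source: %s\n", x$meta$source))
  invisible(x)
}

#' @export
length.gas_series <- function(x) length(x$readings)

#' Quantize readings to the instrument resolution
#'
#' Direct-reading H2S monitors report at 0.1-ppm resolution; readings kept at
#' full precision can be snapped back to that grid. Off by default throughout
#' the package since exported logs already carry whatever precision the
#' instrument wrote.
#'
#' @param series a `gas_series`.
#' @param resolution grid step in ppm (default 0.1).
#' @return the series with `readings` rounded to multiples of `resolution`.
#' @export
quantize_series <- function(series, resolution = 0.1) {
  stopifnot(inherits(series, "gas_series"), resolution > 0)
  series$readings <- round(series$readings / resolution) * resolution
  series$meta$quantized_to <- resolution
  series
}

# Total covered measurement time in seconds (each sample represents one
# logging interval).
series_duration_secs <- function(series) {
  length(series$readings) * series$interval
}
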