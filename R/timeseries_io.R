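#' Read a shift-level sensor log from CSV
#'
#' Reads one shift's H2S log exported as delimited text (comma or semicolon,
#' auto-detected), locates the timestamp and concentration columns, parses
#' timestamps, and returns a validated [gas_series()]. The logging interval is
#' inferred as the median of consecutive timestamp differences.
#'
#' Column detection order for the concentration column: an explicit
#' `column_map` entry, then the first header containing `"ppm"`
#' (case-insensitive), then the second column. The timestamp column is the
#' `column_map` entry, then the first header matching `time`/`date`/`stamp`,
#' then the first column.
#'
#' @param path CSV file path.
#' @param column_map optional named list/vector with entries `timestamp`
#'   and/or `reading` giving column names (or positions) explicitly.
#' @param tolerance relative interval jitter tolerated by validation
#'   (default 0.05; logger clocks drift but the analysis windows are defined
#'   in wall time).
#' @param ts_format optional `strptime`-style format string for instrument
#'   exports that are not ISO-8601.
#' @param tz timezone for parsing (default `"UTC"`).
#' @param fill_max_gap if non-`NULL`, dropped-sample gaps up to this many
#'   seconds are repaired with [fill_short_gaps()] before validation.
#' @param quantize logical; snap readings to 0.1 ppm (default `FALSE`).
#' @return a validated `gas_series` with `meta$source = path`.
#' @section Errors: malformed timestamps or readings raise `h2s_parse_error`
#'   naming the offending row; gaps beyond tolerance raise
#'   `h2s_interval_error` listing them; negative readings raise
#'   `h2s_negative_error` (they are never silently clipped).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("timestamp,h2s_ppm",
#'              "2014-03-10T07:00:00,0.0",
#'              "2014-03-10T07:00:10,0.5",
#'              "2014-03-10T07:00:20,0.0"), f)
#' read_series(f)
#' @export
read_series <- function(path, column_map = NULL, tolerance = 0.05,
                        ts_format = NULL, tz = "UTC", fill_max_gap = NULL,
                        quantize = FALSE) {
  if (!file.exists(path)) {
    h2s_error(sprintf("file not found: %s", path), "h2s_parse_error")
  }
  sep <- detect_separator(path)
  df <- tryCatch(
    utils::read.csv(path, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE),
    error = function(e) h2s_error(sprintf("cannot parse %s: %s", path,
                                          conditionMessage(e)),
                                  "h2s_parse_error"))
  if (ncol(df) < 2 || nrow(df) < 2) {
    h2s_error(sprintf("%s: need >= 2 rows and >= 2 columns (timestamp, ppm)",
                      path), "h2s_parse_error")
  }
  cols <- resolve_columns(names(df), column_map)
  ts_raw <- df[[cols$timestamp]]
  ts <- parse_timestamps(ts_raw, ts_format, tz)
  if (anyNA(ts)) {
    h2s_error(sprintf("%s: malformed timestamp at row %d (%s)", path,
                      which(is.na(ts))[1],
                      as.character(ts_raw[which(is.na(ts))[1]])),
              "h2s_parse_error")
  }
  r_raw <- df[[cols$reading]]
  readings <- suppressWarnings(as.numeric(r_raw))
  if (anyNA(readings)) {
    h2s_error(sprintf("%s: non-numeric reading at row %d (%s)", path,
                      which(is.na(readings))[1],
                      as.character(r_raw[which(is.na(readings))[1]])),
              "h2s_parse_error")
  }
  series <- new_gas_series(ts, readings, infer_interval(ts),
                           meta = list(source = path,
                                       timestamp_column = cols$timestamp,
                                       reading_column = cols$reading))
  if (!is.null(fill_max_gap)) {
    series <- fill_short_gaps(series, max_gap = fill_max_gap)
  }
  series <- validate_series(series, tolerance = tolerance)
  if (isTRUE(quantize)) series <- quantize_series(series)
  series
}

detect_separator <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) h2s_error(sprintf("%s is empty", path), "h2s_parse_error")
  n_semi <- lengths(regmatches(first, gregexpr(";", first, fixed = TRUE)))
  n_comma <- lengths(regmatches(first, gregexpr(",", first, fixed = TRUE)))
  if (n_semi > n_comma) ";" else ","
}

resolve_columns <- function(headers, column_map) {
  pick <- function(key, pattern, fallback) {
    if (!is.null(column_map) && !is.null(column_map[[key]])) {
      sel <- column_map[[key]]
      if (is.numeric(sel)) {
        if (sel < 1 || sel > length(headers)) {
          h2s_error(sprintf("column_map$%s = %s is out of range", key, sel),
                    "h2s_parse_error")
        }
        return(headers[sel])
      }
      if (!sel %in% headers) {
        h2s_error(sprintf("column_map$%s = '%s' not found among: %s", key, sel,
                          paste(headers, collapse = ", ")), "h2s_parse_error")
      }
      return(sel)
    }
    hit <- grep(pattern, headers, ignore.case = TRUE)
    if (length(hit)) headers[hit[1]] else headers[fallback]
  }
  list(timestamp = pick("timestamp", "time|date|stamp", 1L),
       reading = pick("reading", "ppm", 2L))
}

parse_timestamps <- function(x, ts_format, tz) {
  if (inherits(x, "POSIXct")) return(x)
  x <- as.character(x)
  if (!is.null(ts_format)) {
    return(as.POSIXct(x, format = ts_format, tz = tz))
  }
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = tz)
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(x[miss], format = fmt, tz = tz)
  }
  out
}

#' Write a gas series back to CSV
#'
#' Writes the canonical two-column layout `timestamp,h2s_ppm` (ISO-8601
#' timestamps, readings rounded to `digits` decimals). Together with
#' [read_series()] this round-trips any series up to that decimal
#' quantization.
#'
#' @param series a `gas_series`.
#' @param path output file path.
#' @param digits decimal places for readings (default 4).
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, digits = 4) {
  stopifnot(inherits(series, "gas_series"))
  df <- data.frame(
    timestamp = format(series$timestamps, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    h2s_ppm = formatC(round(series$readings, digits), format = "f",
                      digits = digits)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Repair short dropped-sample gaps by linear interpolation
#'
#' Field loggers occasionally drop samples; a short gap (at most `max_gap`
#' seconds between consecutive timestamps) is repaired by inserting evenly
#' spaced samples with linearly interpolated readings. Inserted positions are
#' flagged in `meta$filled_gaps`. Longer gaps are left untouched and remain a
#' validation error downstream — this is a conservative repair, not a
#' reconstruction of missing exposure.
#'
#' @param series a `gas_series`, validated or not.
#' @param max_gap largest timestamp difference (seconds) that will be filled;
#'   must be `>=` the logging interval.
#' @return a `gas_series` (not re-validated; pass through [validate_series()]
#'   or [analyze_shift()] afterwards).
#' @examples
#' ts <- as.POSIXct("2014-03-10 07:00:00", tz = "UTC") + c(0, 10, 30, 40)
#' gappy <- h2sindex:::new_gas_series(ts, c(0, 1, 3, 0), 10)
#' filled <- fill_short_gaps(gappy, max_gap = 30)
#' filled$readings  # 0 1 2 3 0
#' @export
fill_short_gaps <- function(series, max_gap) {
  stopifnot(inherits(series, "gas_series"))
  iv <- series$interval
  if (max_gap < iv) {
    h2s_error(sprintf("max_gap (%g s) must be >= the logging interval (%g s)",
                      max_gap, iv), "h2s_parse_error")
  }
  ts <- series$timestamps
  x <- series$readings
  d <- as.numeric(diff(ts), units = "secs")
  fill <- which(d > 1.5 * iv & d <= max_gap)
  if (length(fill) == 0) return(series)
  new_ts <- list()
  new_x <- list()
  filled_at <- list()
  prev <- 1L
  for (g in fill) {
    new_ts[[length(new_ts) + 1L]] <- ts[prev:g]
    new_x[[length(new_x) + 1L]] <- x[prev:g]
    k <- max(2L, as.integer(round(d[g] / iv)))  # number of sub-intervals
    grid <- ts[g] + seq_len(k - 1L) * (d[g] / k)
    interp <- x[g] + (x[g + 1L] - x[g]) * seq_len(k - 1L) / k
    new_ts[[length(new_ts) + 1L]] <- grid
    new_x[[length(new_x) + 1L]] <- interp
    filled_at[[length(filled_at) + 1L]] <-
      data.frame(after_timestamp = format(ts[g], "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                 n_inserted = k - 1L, gap_secs = d[g])
    prev <- g + 1L
  }
  n <- length(x)
  new_ts[[length(new_ts) + 1L]] <- ts[prev:n]
  new_x[[length(new_x) + 1L]] <- x[prev:n]
  out <- series
  out$timestamps <- do.call(c, new_ts)
  out$readings <- unlist(new_x, use.names = FALSE)
  out$meta$filled_gaps <- do.call(rbind, filled_at)
  out
}
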