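# Shared fixture builders. Everything is generated in code; no data files.

SHIFT_START <- as.POSIXct("2014-03-10 07:00:00", tz = "UTC")

# A gas_series from a readings vector on a regular grid.
make_series <- function(readings, interval = 10, meta = list()) {
  ts <- SHIFT_START + (seq_along(readings) - 1) * interval
  gas_series(ts, readings, interval = interval, meta = meta)
}

# Write a minimal two-column CSV fixture and return its path.
write_csv_fixture <- function(timestamps, readings,
                              header = c("timestamp", "h2s_ppm"),
                              sep = ",", path = tempfile(fileext = ".csv")) {
  lines <- c(paste(header, collapse = sep),
             paste(format(timestamps, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                   readings, sep = sep))
  writeLines(lines, path)
  path
}

# Third, test-tree-only moving-average route: literal window means,
# independent of both the package pipeline and the package oracle.
ref_cma <- function(x, interval, window) {
  w <- round(window / interval)
  if (w %% 2 == 0) w <- w + 1
  h <- (w - 1) / 2
  n <- length(x)
  vapply(seq_len(n),
         function(i) {
           lo <- max(1, i - h)
           hi <- min(n, i + h)
           sum(x[lo:hi]) / (hi - lo + 1)
         },
         numeric(1))
}

# The 8-h single-spike shift used across modules: all zero except one
# 8.0-ppm sample, 10-s logging.
single_spike_shift <- function(n = 2880, spike_at = n %/% 2, value = 8.0,
                               interval = 10) {
  x <- numeric(n)
  x[spike_at] <- value
  make_series(x, interval = interval)
}

# Elements as a plain comparable list (drops the S3 class).
elements_list <- function(e) unclass(e)[c("c01", "c1", "c5", "c10",
                                          "dur01", "dur5", "max_ppm")]
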