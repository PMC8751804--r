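#' Centred moving average over a wall-time window
#'
#' The smoothing primitive behind both task segmentation (3-min window) and
#' peak validation (1-min window). The window is specified in seconds and
#' converted to samples as `w = round(window / logging_interval)`, forced odd
#' (incremented by 1 when even) so the average is truly centred; at the
#' series edges the window shrinks to the available samples and the divisor
#' is the actual sample count, so no unexposed time is fabricated at shift
#' boundaries.
#'
#' The implementation is cumulative-sum based (O(n)); sums of exact zeros
#' stay exactly zero, so the strict `> 0` positivity test used downstream is
#' safe.
#'
#' @param series a `gas_series`.
#' @param window window length in seconds; must be `>=` the logging interval.
#' @return an object of class `smoothed_series`: list with `values` (one
#'   smoothed ppm value per original sample), `window` (seconds), `width`
#'   (odd sample count `w`), `half_width` (`(w-1)/2`), `interval`, `n`.
#' @examples
#' ts <- as.POSIXct("2014-03-10 07:00:00", tz = "UTC") + seq(0, 60, by = 10)
#' s <- gas_series(ts, c(0, 0, 0, 8, 0, 0, 0))
#' centred_moving_average(s, 60)$values  # centre value 8/7, edge value 8/4
#' @export
centred_moving_average <- function(series, window) {
  stopifnot(inherits(series, "gas_series"))
  iv <- series$interval
  if (window < iv) {
    h2s_error(sprintf("window (%g s) must be >= the logging interval (%g s)",
                      window, iv), "h2s_parse_error")
  }
  w <- as.integer(round(window / iv))
  if (w %% 2L == 0L) w <- w + 1L
  h <- (w - 1L) %/% 2L
  x <- series$readings
  n <- length(x)
  idx <- seq_len(n)
  lo <- pmax(idx - h, 1L)
  hi <- pmin(idx + h, n)
  cs <- cumsum(c(0, x))
  vals <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  structure(
    list(values = vals, window = window, width = w, half_width = h,
         interval = iv, n = n),
    class = "smoothed_series"
  )
}

#' @export
print.smoothed_series <- function(x, ...) {
  cat(sprintf("<smoothed_series> %d values, %g-s window (%d samples)\n",
              x$n, x$window, x$width))
  invisible(x)
}
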