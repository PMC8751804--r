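#' Brute-force reference computation of the index elements
#'
#' A deliberately naive, sample-by-sample restatement of the whole method:
#' loop-computed centred moving averages with shrinking edges, a linear walk
#' collecting positive-CMA runs, an explicit merge pass, literal evaluation
#' of both peak criteria at every sample, the at-least-one-peak rule, and
#' counting loops for durations and the maximum. It shares no code with the
#' production pipeline ([analyze_shift()] and friends, which are
#' vectorised / cumulative-sum based), so agreement between the two routes
#' is a meaningful check — the package's test suite asserts exact equality
#' of the elements on seeded synthetic shifts, and [generate_shift()] uses
#' this route to supply ground truth.
#'
#' @param series a validated `gas_series`.
#' @param params an [algorithm_params()] bundle (quantization applied here
#'   too when enabled).
#' @return an [index_elements()] object.
#' @export
oracle_elements <- function(series, params = algorithm_params()) {
  stopifnot(inherits(series, "gas_series"))
  x <- series$readings
  iv <- series$interval
  n <- length(x)
  if (isTRUE(params$quantize)) {
    for (i in seq_len(n)) x[i] <- round(x[i] / params$quantize_to) * params$quantize_to
  }

  cma3 <- oracle_cma(x, iv, params$cma_window)
  cma1 <- oracle_cma(x, iv, params$peak_cma_window)

  # positive-CMA runs, collected by a linear walk
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (cma3[i] > 0) {
      j <- i
      while (j < n && cma3[j + 1L] > 0) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }

  # merge runs separated by a zero-CMA gap shorter than the separation time
  tasks <- list()
  for (r in runs) {
    if (length(tasks) == 0) {
      tasks[[1L]] <- r
    } else {
      last <- tasks[[length(tasks)]]
      gap_secs <- (r[1L] - last[2L] - 1L) * iv
      if (gap_secs < params$separation) {
        tasks[[length(tasks)]] <- c(last[1L], r[2L])
      } else {
        tasks[[length(tasks) + 1L]] <- r
      }
    }
  }

  # literal evaluation of both peak criteria within each task
  c01 <- 0L; c1 <- 0L; c5 <- 0L; c10 <- 0L
  for (t in tasks) {
    apexes <- numeric(0)
    for (i in t[1L]:t[2L]) {
      left_ok <- if (i == 1L) TRUE else x[i] > x[i - 1L]
      right_ok <- if (i == n) TRUE else x[i] > x[i + 1L]
      is_local_max <- left_ok && right_ok && x[i] > 0
      meets_ratio <- x[i] >= params$ratio * cma1[i]
      if (is_local_max && meets_ratio) apexes <- c(apexes, x[i])
    }
    if (length(apexes) == 0) {
      # at-least-one rule: the task maximum stands in as the single peak
      m <- x[t[1L]]
      for (i in t[1L]:t[2L]) if (x[i] > m) m <- x[i]
      apexes <- m
    }
    for (a in apexes) {
      if (a <= 1) c01 <- c01 + 1L
      else if (a <= 5) c1 <- c1 + 1L
      else if (a <= 10) c5 <- c5 + 1L
      else c10 <- c10 + 1L
    }
  }

  # data points are counted per band, then converted to time once
  n01 <- 0L; n5 <- 0L; mx <- 0
  for (i in seq_len(n)) {
    if (x[i] > 0 && x[i] <= 5) n01 <- n01 + 1L
    if (x[i] > 5) n5 <- n5 + 1L
    if (x[i] > mx) mx <- x[i]
  }

  index_elements(c01 = c01, c1 = c1, c5 = c5, c10 = c10,
                 dur01 = n01 * iv / 60, dur5 = n5 * iv / 60, max_ppm = mx)
}

# O(n * w) moving average: explicit window mean at every sample.
oracle_cma <- function(x, interval, window) {
  w <- round(window / interval)
  if (w %% 2 == 0) w <- w + 1
  h <- (w - 1) / 2
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - h)
    hi <- min(n, i + h)
    out[i] <- sum(x[lo:hi]) / (hi - lo + 1)
  }
  out
}

# Literal restatement of the index equation, independent of compute_index().
oracle_index <- function(e) {
  e$c01 * 0.1 + e$dur01 * 0.1 + e$c1 + e$c5 * 5 + e$dur5 * 5 + e$c10 * 10 +
    e$max_ppm
}
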