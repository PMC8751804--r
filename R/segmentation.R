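#' Segment a shift into exposure tasks
#'
#' An exposure task (exposure incident) is a maximal run of samples whose
#' 3-min centred moving average (CMA) is strictly positive. Runs separated by
#' an all-zero-CMA gap shorter than `separation` seconds are merged into one
#' task: distinct tasks must be separated by at least that much unexposed
#' time. With the default 3-min window the CMA itself already bridges short
#' raw gaps, so merging mostly matters when the two parameters are set
#' independently (both are adjustable to fit other work patterns).
#'
#' @param series a validated `gas_series`.
#' @param cma_window CMA window in seconds (default 180 = 3 min).
#' @param separation minimum unexposed time between distinct tasks, seconds
#'   (default 180 = 3 min).
#' @return a data frame with one row per task, ordered by start time:
#'   `task_id`, `start_index`, `end_index` (1-based sample indices, both
#'   inclusive), `start_time`, `end_time`, `n_samples`,
#'   `duration_min` (= `n_samples * interval / 60`), `max_ppm`. An
#'   unexposed shift yields zero rows.
#' @examples
#' ts <- as.POSIXct("2014-03-10 07:00:00", tz = "UTC") + seq(0, 990, by = 10)
#' x <- numeric(100); x[21] <- 2.0
#' segment_tasks(gas_series(ts, x))  # one ~3.2-min task around sample 21
#' @export
segment_tasks <- function(series, cma_window = 180, separation = 180) {
  stopifnot(inherits(series, "gas_series"))
  cma <- centred_moving_average(series, cma_window)$values
  runs <- positive_runs(cma > 0)
  runs <- merge_runs(runs, gap_secs = series$interval, separation = separation)
  task_table(series, runs)
}

# Maximal TRUE runs as a two-column matrix (start, end), 1-based inclusive.
positive_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Merge consecutive runs whose separating gap (in seconds) is shorter than
# `separation`. gap_secs is the per-sample duration.
merge_runs <- function(runs, gap_secs, separation) {
  if (nrow(runs) < 2) return(runs)
  out <- runs[1, , drop = FALSE]
  for (i in 2:nrow(runs)) {
    gap <- (runs[i, "start"] - out[nrow(out), "end"] - 1L) * gap_secs
    if (gap < separation) {
      out[nrow(out), "end"] <- runs[i, "end"]
    } else {
      out <- rbind(out, runs[i, , drop = FALSE])
    }
  }
  out
}

empty_task_table <- function() {
  data.frame(
    task_id = integer(0), start_index = integer(0), end_index = integer(0),
    start_time = as.POSIXct(character(0), tz = "UTC"),
    end_time = as.POSIXct(character(0), tz = "UTC"),
    n_samples = integer(0), duration_min = numeric(0), max_ppm = numeric(0)
  )
}

task_table <- function(series, runs) {
  n <- nrow(runs)
  if (is.null(n) || n == 0) return(empty_task_table())
  ns <- runs[, "end"] - runs[, "start"] + 1L
  data.frame(
    task_id = seq_len(n),
    start_index = as.integer(runs[, "start"]),
    end_index = as.integer(runs[, "end"]),
    start_time = series$timestamps[runs[, "start"]],
    end_time = series$timestamps[runs[, "end"]],
    n_samples = as.integer(ns),
    duration_min = ns * series$interval / 60,
    max_ppm = vapply(seq_len(n), function(i) {
      max(series$readings[runs[i, "start"]:runs[i, "end"]])
    }, numeric(1)),
    row.names = NULL
  )
}

#' Indices of raw-positive samples
#'
#' Samples with a strictly positive raw reading — the exposed data points
#' used for duration accumulation and the exposed-period summary statistics.
#' Distinct from (and always a subset of) the CMA-positive support that
#' defines tasks.
#'
#' @param series a `gas_series`.
#' @return integer vector of 1-based sample indices.
#' @export
exposed_samples <- function(series) {
  stopifnot(inherits(series, "gas_series"))
  which(series$readings > 0)
}

#' Export the per-task table as CSV
#'
#' Writes `task_id,start,end,duration_min,max_ppm,n_peaks` for one shift.
#'
#' @param tasks task table from [segment_tasks()].
#' @param peaks peak table from [detect_peaks()] (used for per-task counts).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_task_csv <- function(tasks, peaks, path) {
  n_peaks <- vapply(tasks$task_id, function(id) sum(peaks$task_id == id),
                    integer(1))
  df <- data.frame(
    task_id = tasks$task_id,
    start = format(tasks$start_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    end = format(tasks$end_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    duration_min = tasks$duration_min,
    max_ppm = tasks$max_ppm,
    n_peaks = n_peaks
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
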