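#' Concentration interval classes for peak apexes
#'
#' Apex concentrations are classified into four half-open intervals,
#' `(0, 1]`, `(1, 5]`, `(5, 10]` and `(10, Inf)` ppm, labelled `I01`, `I1`,
#' `I5`, `I10`. The cut points follow the regulatory levels relevant to H2S
#' (1 ppm threshold, 5 ppm 8-h OEL, 10 ppm ceiling); at the instrument's
#' 0.1-ppm resolution the half-open convention reproduces the printed labels
#' "up to 1.0", "1.1-5.0", "5.1-10.0", "10.1 and higher".
#'
#' @param apex numeric vector of apex concentrations, ppm, `> 0`.
#' @return factor with levels `I01`, `I1`, `I5`, `I10`.
#' @export
classify_interval <- function(apex) {
  stopifnot(all(apex > 0))
  cut(apex, breaks = c(0, 1, 5, 10, Inf), labels = c("I01", "I1", "I5", "I10"),
      right = TRUE)
}

#' Detect distinct peaks within exposure tasks
#'
#' A sample is a peak when it satisfies both criteria: (1) its raw reading is
#' strictly larger than both the previous and the next reading (shift
#' boundary samples compare only against the neighbour that exists), and
#' (2) the reading is at least `ratio` times the 1-min centred moving
#' average at that sample (default 1.25, i.e. 25% above the local average —
#' this rejects slow drifts whose every point hugs its own local mean, and
#' it is scale-free). A dip towards zero inside a task does not by itself
#' start a new peak; only a new qualifying local maximum does.
#'
#' Every task contributes at least one peak: when no sample in a task
#' satisfies both criteria (e.g. a plateau, or a slow symmetric ramp), one
#' forced peak is emitted at the earliest sample attaining the task's
#' maximum reading, flagged `forced = TRUE`.
#'
#' @param series the validated `gas_series` the tasks were segmented from.
#' @param tasks task table from [segment_tasks()] (or a subset of its rows).
#' @param peak_cma_window window for the validating CMA, seconds
#'   (default 60 = 1 min).
#' @param ratio required apex-to-CMA ratio (default 1.25).
#' @return a data frame ordered by sample index: `task_id`, `index` (1-based
#'   apex sample), `time`, `apex_ppm` (raw reading), `interval` (factor, see
#'   [classify_interval()]), `forced`.
#' @export
detect_peaks <- function(series, tasks, peak_cma_window = 60, ratio = 1.25) {
  stopifnot(inherits(series, "gas_series"))
  if (nrow(tasks) == 0) return(empty_peak_table())
  x <- series$readings
  n <- length(x)
  iv <- series$interval
  if (peak_cma_window < iv) {
    h2s_error(sprintf("peak_cma_window (%g s) must be >= the logging interval (%g s)",
                      peak_cma_window, iv), "h2s_parse_error")
  }
  w <- as.integer(round(peak_cma_window / iv))
  if (w %% 2L == 0L) w <- w + 1L
  h <- (w - 1L) %/% 2L
  # strict local maximum over the full series (task-boundary samples still
  # compare against their real neighbours; only shift boundaries are one-sided)
  gt_prev <- c(TRUE, x[-1] > x[-n])
  gt_next <- c(x[-n] > x[-1], TRUE)
  local_max <- gt_prev & gt_next & x > 0
  # criterion 2 only needs evaluating at the (sparse) local maxima; the
  # window mean is computed literally there, because quantized readings make
  # exact ties (apex == ratio * CMA) routine and a running-sum average can be
  # off by an ulp right where the comparison must be exact
  qualifies <- logical(n)
  for (i in which(local_max)) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    qualifies[i] <- x[i] >= ratio * (sum(x[lo:hi]) / (hi - lo + 1L))
  }

  out <- lapply(seq_len(nrow(tasks)), function(i) {
    s <- tasks$start_index[i]
    e <- tasks$end_index[i]
    idx <- s:e
    hits <- idx[qualifies[idx]]
    forced <- FALSE
    if (length(hits) == 0) {
      # at-least-one rule: earliest sample attaining the task maximum
      hits <- idx[which.max(x[idx])]
      forced <- TRUE
    }
    data.frame(task_id = tasks$task_id[i], index = hits,
               apex_ppm = x[hits], forced = forced)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$index), , drop = FALSE]
  data.frame(
    task_id = out$task_id,
    index = out$index,
    time = series$timestamps[out$index],
    apex_ppm = out$apex_ppm,
    interval = classify_interval(out$apex_ppm),
    forced = out$forced,
    row.names = NULL
  )
}

empty_peak_table <- function() {
  data.frame(
    task_id = integer(0), index = integer(0),
    time = as.POSIXct(character(0), tz = "UTC"),
    apex_ppm = numeric(0),
    interval = factor(character(0), levels = c("I01", "I1", "I5", "I10")),
    forced = logical(0)
  )
}

#' Count peaks per concentration interval
#'
#' Partitions a peak list into the four interval counts that feed the index:
#' `c01` (apex in (0,1] ppm), `c1` ((1,5]), `c5` ((5,10]), `c10` (above 10).
#'
#' @param peaks peak table from [detect_peaks()].
#' @return named integer vector `c(c01, c1, c5, c10)`; the counts always sum
#'   to `nrow(peaks)`.
#' @export
count_peaks_by_interval <- function(peaks) {
  tab <- table(factor(peaks$interval, levels = c("I01", "I1", "I5", "I10")))
  stats::setNames(as.integer(tab), c("c01", "c1", "c5", "c10"))
}

#' Export the per-peak table as CSV
#'
#' Writes `task_id,peak_time,apex_ppm,interval,forced` for one shift.
#'
#' @param peaks peak table from [detect_peaks()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peak_csv <- function(peaks, path) {
  df <- data.frame(
    task_id = peaks$task_id,
    peak_time = format(peaks$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    apex_ppm = peaks$apex_ppm,
    interval = as.character(peaks$interval),
    forced = peaks$forced
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
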