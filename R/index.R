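#' Algorithm parameters
#'
#' Bundles every tunable the pipeline uses, with defaults equal to the
#' published choices: 3-min segmentation CMA, 3-min task separation, 1-min
#' peak-validation CMA, 1.25 apex-to-CMA ratio, 8-h TWA reference, no
#' quantization. The separation time (and the rest) can be modified to fit
#' other work patterns.
#'
#' @param cma_window segmentation CMA window, seconds.
#' @param separation minimum unexposed time between tasks, seconds.
#' @param peak_cma_window peak-validation CMA window, seconds.
#' @param ratio required apex-to-CMA ratio (dimensionless).
#' @param reference_hours TWA reference period, hours.
#' @param quantize logical; snap readings to `quantize_to` ppm before
#'   analysis.
#' @param quantize_to quantization grid, ppm.
#' @return an object of class `algorithm_params` (named list).
#' @export
algorithm_params <- function(cma_window = 180, separation = 180,
                             peak_cma_window = 60, ratio = 1.25,
                             reference_hours = 8, quantize = FALSE,
                             quantize_to = 0.1) {
  stopifnot(cma_window > 0, separation >= 0, peak_cma_window > 0,
            ratio > 0, reference_hours > 0, quantize_to > 0)
  structure(
    list(cma_window = cma_window, separation = separation,
         peak_cma_window = peak_cma_window, ratio = ratio,
         reference_hours = reference_hours, quantize = quantize,
         quantize_to = quantize_to),
    class = "algorithm_params"
  )
}

#' The seven index elements of one shift
#'
#' Container for the components the exposure index is built from: the peak
#' counts in four apex-concentration intervals (`c01`, `c1`, `c5`, `c10`),
#' the exposed durations in two concentration bands (`dur01` for readings in
#' (0, 5] ppm, `dur5` for readings above 5 ppm, both in minutes), and the
#' maximum raw reading of the whole measurement (`max_ppm`).
#'
#' @param c01,c1,c5,c10 non-negative integer peak counts.
#' @param dur01,dur5 exposed durations in minutes.
#' @param max_ppm maximum raw reading, ppm.
#' @return an object of class `index_elements`.
#' @export
index_elements <- function(c01 = 0L, c1 = 0L, c5 = 0L, c10 = 0L,
                           dur01 = 0, dur5 = 0, max_ppm = 0) {
  counts <- c(c01, c1, c5, c10)
  stopifnot(all(counts >= 0), all(counts == round(counts)),
            dur01 >= 0, dur5 >= 0, max_ppm >= 0)
  structure(
    list(c01 = as.integer(c01), c1 = as.integer(c1), c5 = as.integer(c5),
         c10 = as.integer(c10), dur01 = as.numeric(dur01),
         dur5 = as.numeric(dur5), max_ppm = as.numeric(max_ppm)),
    class = "index_elements"
  )
}

#' @export
print.index_elements <- function(x, ...) {
  cat(sprintf(
    "<index_elements> peaks %d/%d/%d/%d (c01/c1/c5/c10), dur01 %.3g min, dur5 %.3g min, max %.3g ppm\n",
    x$c01, x$c1, x$c5, x$c10, x$dur01, x$dur5, x$max_ppm))
  invisible(x)
}

#' Default index weights
#'
#' The published weighting of the seven elements: 0.1 per peak up to 1 ppm,
#' 0.1 per exposed minute up to 5 ppm, 1 per peak in (1, 5] ppm, 5 per peak
#' in (5, 10] ppm, 5 per exposed minute above 5 ppm, 10 per peak above
#' 10 ppm, plus the shift maximum (weight 1). Alternative weightings alter
#' the meaning of the index and would need re-validation.
#'
#' @return named numeric vector with entries `c01`, `dur01`, `c1`, `c5`,
#'   `dur5`, `c10`, `max`.
#' @export
index_weights <- function() {
  c(c01 = 0.1, dur01 = 0.1, c1 = 1, c5 = 5, dur5 = 5, c10 = 10, max = 1)
}

#' Evaluate the exposure index
#'
#' The dimensionless exposure index of one shift is the weighted sum of the
#' seven elements:
#'
#' `index = c01*0.1 + dur01*0.1 + c1*1 + c5*5 + dur5*5 + c10*10 + max_ppm`
#'
#' with durations in minutes. It combines frequency (peak counts), duration
#' (exposed time below/above the 5-ppm OEL) and intensity (the shift
#' maximum) into one hazard number, so that shifts with brief but severe
#' peaks rank high even when their TWA is negligible.
#'
#' @param elements an `index_elements` object.
#' @param weights weight vector as from [index_weights()].
#' @return a single non-negative number.
#' @examples
#' compute_index(index_elements(c01 = 1, c5 = 1, dur01 = 2, dur5 = 0.5,
#'                              max_ppm = 8))  # 15.8
#' @export
compute_index <- function(elements, weights = index_weights()) {
  stopifnot(inherits(elements, "index_elements"))
  stopifnot(all(c("c01", "dur01", "c1", "c5", "dur5", "c10", "max") %in%
                  names(weights)))
  elements$c01 * weights[["c01"]] +
    elements$dur01 * weights[["dur01"]] +
    elements$c1 * weights[["c1"]] +
    elements$c5 * weights[["c5"]] +
    elements$dur5 * weights[["dur5"]] +
    elements$c10 * weights[["c10"]] +
    elements$max_ppm * weights[["max"]]
}

#' Accumulate exposed durations in the two index bands
#'
#' Each sample with a positive raw reading contributes one logging interval
#' to `dur01` when the reading is in (0, 5] ppm, or to `dur5` when above
#' 5 ppm. Zero readings contribute to neither band: unexposed time carries no
#' hazard, so a fully unexposed shift keeps index 0.
#'
#' @param series a `gas_series`.
#' @return named numeric vector `c(dur01, dur5)` in minutes.
#' @export
accumulate_durations <- function(series) {
  stopifnot(inherits(series, "gas_series"))
  x <- series$readings
  # samples are counted first, then converted to minutes once
  c(dur01 = sum(x > 0 & x <= 5) * series$interval / 60,
    dur5 = sum(x > 5) * series$interval / 60)
}

#' Time-weighted average and measurement-time mean
#'
#' The exposure dose is `sum(reading * logging_interval)` (ppm-minutes).
#' `mean_measured` divides by the measured time; `twa` divides by the
#' reference period (default 8 h), treating time outside the measurement as
#' unexposed — measurements covered the active work, so the 8-h TWA is the
#' number to set against an 8-h OEL.
#'
#' @param series a `gas_series`.
#' @param reference_hours reference period in hours (default 8); must be
#'   positive.
#' @return list with `twa_8h` (ppm), `mean_measured` (ppm), `dose_ppm_min`,
#'   `duration_min`.
#' @export
compute_twa <- function(series, reference_hours = 8) {
  stopifnot(inherits(series, "gas_series"))
  if (reference_hours <= 0) {
    h2s_error("reference_hours must be positive", "h2s_parse_error")
  }
  dose <- sum(series$readings) * series$interval / 60  # ppm-minutes
  duration_min <- series_duration_secs(series) / 60
  list(twa_8h = dose / (reference_hours * 60),
       mean_measured = dose / duration_min,
       dose_ppm_min = dose,
       duration_min = duration_min)
}

#' Summary statistics of the exposed readings
#'
#' Median, geometric mean and geometric standard deviation over the strictly
#' positive raw readings, the lognormal-style summaries conventional in
#' exposure assessment: `gm = exp(mean(log r))`,
#' `gsd = exp(sd(log r))` with the sample (n-1) standard deviation. With no
#' positive readings all statistics are `NA`; with a single positive reading
#' the GSD is `NA`.
#'
#' @param series a `gas_series`.
#' @return list with `n_exposed`, `median`, `gm`, `gsd` (ppm except the
#'   dimensionless `gsd`).
#' @export
exposed_summary <- function(series) {
  stopifnot(inherits(series, "gas_series"))
  r <- series$readings[series$readings > 0]
  if (length(r) == 0) {
    return(list(n_exposed = 0L, median = NA_real_, gm = NA_real_,
                gsd = NA_real_))
  }
  lr <- log(r)
  list(
    n_exposed = length(r),
    median = stats::median(r),
    gm = exp(mean(lr)),
    gsd = if (length(r) >= 2) exp(stats::sd(lr)) else NA_real_
  )
}

#' Analyze one shift end to end
#'
#' Runs the full pipeline on a validated series: optional quantization,
#' task segmentation, peak detection and classification, duration
#' accumulation, index evaluation, TWA, and exposed-period summaries. The
#' returned report records every parameter used, so a report is reproducible
#' from its own provenance.
#'
#' @param series a `gas_series` (re-validated here).
#' @param params an [algorithm_params()] bundle.
#' @return an object of class `shift_report`: list with `elements`
#'   ([index_elements()]), `index`, `twa_8h`, `mean_measured`,
#'   `measurement_duration_h`, `n_samples`, `n_tasks`, `task_durations_min`,
#'   `exposed_median`, `exposed_gm`, `exposed_gsd`, `n_exposed`, `tasks`,
#'   `peaks`, `params`, `source`.
#' @examples
#' ts <- as.POSIXct("2014-03-10 07:00:00", tz = "UTC") + seq(0, 990, by = 10)
#' x <- numeric(100); x[51] <- 8.0
#' rep <- analyze_shift(gas_series(ts, x))
#' rep$index  # 5 + (10/60)*5 + 8 = 13.8333...
#' @export
analyze_shift <- function(series, params = algorithm_params()) {
  stopifnot(inherits(series, "gas_series"), inherits(params, "algorithm_params"))
  validate_series(series)
  if (isTRUE(params$quantize)) {
    series <- quantize_series(series, params$quantize_to)
  }
  tasks <- segment_tasks(series, cma_window = params$cma_window,
                         separation = params$separation)
  peaks <- detect_peaks(series, tasks,
                        peak_cma_window = params$peak_cma_window,
                        ratio = params$ratio)
  counts <- count_peaks_by_interval(peaks)
  durs <- accumulate_durations(series)
  elements <- index_elements(
    c01 = counts[["c01"]], c1 = counts[["c1"]], c5 = counts[["c5"]],
    c10 = counts[["c10"]], dur01 = durs[["dur01"]], dur5 = durs[["dur5"]],
    max_ppm = max(series$readings)
  )
  twa <- compute_twa(series, params$reference_hours)
  ex <- exposed_summary(series)
  structure(
    list(
      elements = elements,
      index = compute_index(elements),
      twa_8h = twa$twa_8h,
      mean_measured = twa$mean_measured,
      measurement_duration_h = twa$duration_min / 60,
      n_samples = length(series$readings),
      n_tasks = nrow(tasks),
      task_durations_min = tasks$duration_min,
      exposed_median = ex$median,
      exposed_gm = ex$gm,
      exposed_gsd = ex$gsd,
      n_exposed = ex$n_exposed,
      tasks = tasks,
      peaks = peaks,
      params = unclass(params),
      source = if (is.null(series$meta$source)) NA_character_ else series$meta$source
    ),
    class = "shift_report"
  )
}

#' @export
print.shift_report <- function(x, ...) {
  cat(sprintf("<shift_report> %s\n",
              if (is.na(x$source)) "(in-memory series)" else x$source))
  cat(sprintf("  index %.4g | TWA(8h) %.4g ppm | mean over %.2f h: %.4g ppm\n",
              x$index, x$twa_8h, x$measurement_duration_h, x$mean_measured))
  e <- x$elements
  cat(sprintf("  %d task(s), peaks %d/%d/%d/%d (c01/c1/c5/c10), dur01 %.3g min, dur5 %.3g min, max %.3g ppm\n",
              x$n_tasks, e$c01, e$c1, e$c5, e$c10, e$dur01, e$dur5, e$max_ppm))
  if (x$n_exposed > 0) {
    cat(sprintf("  exposed: n %d, median %.3g, GM %.3g, GSD %s\n",
                x$n_exposed, x$exposed_median, x$exposed_gm,
                ifelse(is.na(x$exposed_gsd), "NA", sprintf("%.3g", x$exposed_gsd))))
  }
  invisible(x)
}
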