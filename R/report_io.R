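#' Write a shift report to disk
#'
#' `format = "json"` writes the full report (elements, index, TWA,
#' summaries, per-task and per-peak tables, parameters) at full numeric
#' precision, so [read_report()] reproduces every numeric field exactly.
#' `format = "csv"` writes the one-line batch summary row
#' (`file,index,twa_8h,mean_ppm,max_ppm,n_tasks,c01,c1,c5,c10,dur01_min,dur5_min`)
#' with header.
#'
#' @param report a `shift_report` from [analyze_shift()].
#' @param path output file path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  stopifnot(inherits(report, "shift_report"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(report_summary_row(report), path, row.names = FALSE,
                     quote = FALSE)
    return(invisible(path))
  }
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = I(17), null = "null", na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a JSON shift report back
#'
#' Inverse of [write_report()] for the JSON format: every numeric field of
#' the returned `shift_report` equals the written one exactly.
#'
#' @param path JSON report path.
#' @return a `shift_report`.
#' @export
read_report <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  list_to_report(l)
}

report_summary_row <- function(report) {
  e <- report$elements
  data.frame(
    file = if (is.na(report$source)) "" else basename(report$source),
    index = report$index,
    twa_8h = report$twa_8h,
    mean_ppm = report$mean_measured,
    max_ppm = e$max_ppm,
    n_tasks = report$n_tasks,
    c01 = e$c01, c1 = e$c1, c5 = e$c5, c10 = e$c10,
    dur01_min = e$dur01, dur5_min = e$dur5
  )
}

fmt_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

report_to_list <- function(report) {
  tasks <- report$tasks
  tasks$start_time <- fmt_time(tasks$start_time)
  tasks$end_time <- fmt_time(tasks$end_time)
  peaks <- report$peaks
  peaks$time <- fmt_time(peaks$time)
  peaks$interval <- as.character(peaks$interval)
  list(
    schema = "h2sindex/shift_report/v1",
    source = report$source,
    index = report$index,
    elements = unclass(report$elements),
    twa_8h = report$twa_8h,
    mean_measured = report$mean_measured,
    measurement_duration_h = report$measurement_duration_h,
    n_samples = report$n_samples,
    n_tasks = report$n_tasks,
    task_durations_min = report$task_durations_min,
    exposed = list(n = report$n_exposed, median = report$exposed_median,
                   gm = report$exposed_gm, gsd = report$exposed_gsd),
    tasks = tasks,
    peaks = peaks,
    params = report$params
  )
}

list_to_report <- function(l) {
  as_df_times <- function(df, cols) {
    df <- as.data.frame(df)
    for (cl in cols) df[[cl]] <- as.POSIXct(df[[cl]], tz = "UTC",
                                            format = "%Y-%m-%dT%H:%M:%S")
    df
  }
  e <- l$elements
  tasks <- if (length(l$tasks)) {
    as_df_times(l$tasks, c("start_time", "end_time"))
  } else {
    empty_task_table()
  }
  peaks <- if (length(l$peaks)) {
    p <- as_df_times(l$peaks, "time")
    p$interval <- factor(p$interval, levels = c("I01", "I1", "I5", "I10"))
    p
  } else {
    empty_peak_table()
  }
  structure(
    list(
      elements = index_elements(e$c01, e$c1, e$c5, e$c10, e$dur01, e$dur5,
                                e$max_ppm),
      index = as.numeric(l$index),
      twa_8h = as.numeric(l$twa_8h),
      mean_measured = as.numeric(l$mean_measured),
      measurement_duration_h = as.numeric(l$measurement_duration_h),
      n_samples = l$n_samples,
      n_tasks = l$n_tasks,
      task_durations_min = as.numeric(unlist(l$task_durations_min)),
      exposed_median = null_na(l$exposed$median),
      exposed_gm = null_na(l$exposed$gm),
      exposed_gsd = null_na(l$exposed$gsd),
      n_exposed = l$exposed$n,
      tasks = tasks,
      peaks = peaks,
      params = l$params,
      source = if (is.null(l$source)) NA_character_ else l$source
    ),
    class = "shift_report"
  )
}

null_na <- function(x) if (is.null(x) || length(x) == 0) NA_real_ else as.numeric(x)

#' Write a batch summary CSV
#'
#' One row per shift in the batch schema of [write_report()], sorted by
#' descending index so the shifts that most need attention come first.
#'
#' @param reports list of `shift_report` objects.
#' @param path output file.
#' @return the summary data frame, invisibly.
#' @export
write_batch_csv <- function(reports, path) {
  rows <- do.call(rbind, lapply(reports, report_summary_row))
  rows <- rows[order(-rows$index), , drop = FALSE]
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(rows)
}
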