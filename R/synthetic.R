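#' Scenario specification for the synthetic shift generator
#'
#' Describes one simulated work shift: mostly-zero background over several
#' hours, `n_tasks` episodic exposure tasks, each made of one or more
#' instantaneous-rise / exponential-decay pulses with lognormally
#' distributed apex concentrations. The defaults emulate the structure of
#' wastewater-work H2S logs: shifts of a few hours logged at 10 s, a
#' handful of tasks lasting minutes, positive readings with geometric mean
#' 1.8 ppm and geometric standard deviation 9.3, and occasional peaks above
#' 10 ppm.
#'
#' @param shift_hours shift length in hours (default 3).
#' @param logging_interval seconds between samples (default 10).
#' @param n_tasks number of exposure tasks (default 3; 0 gives an
#'   all-zero shift).
#' @param task_start_times optional numeric vector of task start offsets in
#'   seconds from shift start; default `NULL` places tasks at random subject
#'   to the `task_gap` guard.
#' @param peak_amplitude_gm geometric mean of pulse apexes, ppm
#'   (default 1.8).
#' @param peak_amplitude_gsd geometric standard deviation of pulse apexes
#'   (default 9.3, `> 1`).
#' @param peaks_per_task integer vector of candidate pulse counts per task;
#'   one value is drawn uniformly per task (default `1:3`).
#' @param peak_spacing maximum spacing between consecutive pulse starts
#'   within a task, seconds (default 150; actual spacings are uniform on
#'   `[0.3, 1] * peak_spacing`). Keep below `task_gap` minus the pulse tail
#'   so a task cannot split.
#' @param decay_tau exponential decay time constant of each pulse, seconds
#'   (default 30: steep peaks lasting a few minutes).
#' @param quantize_to instrument resolution applied after pulse synthesis,
#'   ppm (default 0.1); `NULL` keeps full precision.
#' @param task_gap guaranteed all-zero time between consecutive tasks,
#'   seconds (default 360 = separation + CMA window, so segmentation
#'   recovers the generated tasks exactly).
#' @param seed integer seed; the same spec and seed give a bit-identical
#'   series. `NULL` uses the current RNG state.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(shift_hours = 3, logging_interval = 10, n_tasks = 3,
                          task_start_times = NULL, peak_amplitude_gm = 1.8,
                          peak_amplitude_gsd = 9.3, peaks_per_task = 1:3,
                          peak_spacing = 150, decay_tau = 30,
                          quantize_to = 0.1, task_gap = 360, seed = NULL) {
  stopifnot(shift_hours > 0, logging_interval > 0, n_tasks >= 0,
            peak_amplitude_gm > 0, peak_amplitude_gsd > 1,
            all(peaks_per_task >= 1), peak_spacing > 0, decay_tau > 0,
            is.null(quantize_to) || quantize_to > 0, task_gap >= 0)
  structure(
    list(shift_hours = shift_hours, logging_interval = logging_interval,
         n_tasks = as.integer(n_tasks), task_start_times = task_start_times,
         peak_amplitude_gm = peak_amplitude_gm,
         peak_amplitude_gsd = peak_amplitude_gsd,
         peaks_per_task = as.integer(peaks_per_task),
         peak_spacing = peak_spacing, decay_tau = decay_tau,
         quantize_to = quantize_to, task_gap = task_gap, seed = seed),
    class = "scenario_spec"
  )
}

#' Draw lognormal pulse apex concentrations
#'
#' Apex amplitudes are lognormal, parameterised by geometric mean and
#' geometric standard deviation: `rlnorm(n, log(gm), log(gsd))`. This is the
#' amplitude model of [generate_shift()]; exposed readings in field data are
#' conventionally summarised by GM/GSD, implying an approximately lognormal
#' distribution.
#'
#' @param n number of draws.
#' @param gm geometric mean, ppm.
#' @param gsd geometric standard deviation (`> 1`).
#' @return numeric vector of apex concentrations, ppm.
#' @export
sample_apex <- function(n, gm = 1.8, gsd = 9.3) {
  stopifnot(gm > 0, gsd > 1)
  stats::rlnorm(n, meanlog = log(gm), sdlog = log(gsd))
}

# Run fn() under a seed without disturbing the caller's RNG state.
with_preserved_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  fn()
}

resample1 <- function(v) if (length(v) == 1L) v else sample(v, 1L)

# Contributions below this are written as exact zeros during synthesis
# (a tenth of the instrument resolution).
PULSE_FLOOR <- 0.01

#' Generate a synthetic shift with oracle ground truth
#'
#' Synthesises one shift according to a [scenario_spec()]: zero background,
#' pulses with instantaneous rise and exponential decay (time constant
#' `decay_tau`), lognormal apexes, optional quantization to the instrument
#' resolution, and task placement that guarantees at least `task_gap`
#' seconds of zeros between consecutive tasks. Ground-truth index elements
#' are computed by the independent brute-force route ([oracle_elements()]),
#' never by the production pipeline, so generator output can arbitrate
#' between the two.
#'
#' Because apexes are lognormal, a small fraction of pulses falls below half
#' the quantization resolution and disappears from the quantized series; the
#' ground truth therefore records the *realized* task windows (those with at
#' least one positive sample), which is what segmentation can recover.
#'
#' @param spec a [scenario_spec()].
#' @param params [algorithm_params()] used for the oracle ground truth.
#' @return list with `series` (a validated `gas_series`) and `truth`, a list
#'   holding `task_windows` (data frame of realized windows: `task_id`,
#'   `start_index`, `end_index`, `start_secs`, `end_secs`),
#'   `peak_apexes` (data frame of nominal pulse times and amplitudes),
#'   `elements` ([index_elements()] by the oracle), `index` (literal
#'   weighted sum), `n_tasks_nominal`, `n_tasks_realized`.
#' @examples
#' sim <- generate_shift(scenario_spec(n_tasks = 2, seed = 7))
#' sim$truth$n_tasks_realized
#' nrow(segment_tasks(sim$series))
#' @export
generate_shift <- function(spec, params = algorithm_params()) {
  stopifnot(inherits(spec, "scenario_spec"))
  with_preserved_seed(spec$seed, function() generate_shift_impl(spec, params))
}

generate_shift_impl <- function(spec, params) {
  iv <- spec$logging_interval
  shift_secs <- spec$shift_hours * 3600
  n <- as.integer(round(shift_secs / iv))
  if (n < 2) h2s_error("shift too short for its logging interval",
                       "h2s_parse_error")
  origin <- as.POSIXct("2014-03-10 07:00:00", tz = "UTC")
  ts <- origin + (seq_len(n) - 1L) * iv
  x <- numeric(n)
  tau <- spec$decay_tau

  pulses <- list()   # per task: data.frame(offset_secs, apex)
  extents <- numeric(spec$n_tasks)
  for (j in seq_len(spec$n_tasks)) {
    k <- resample1(spec$peaks_per_task)
    spacing <- if (k > 1) {
      stats::runif(k - 1, 0.3 * spec$peak_spacing, spec$peak_spacing)
    } else {
      numeric(0)
    }
    offs <- c(0, cumsum(spacing))
    amp <- sample_apex(k, spec$peak_amplitude_gm, spec$peak_amplitude_gsd)
    tail_secs <- pmax(0, tau * log(pmax(amp, PULSE_FLOOR) / PULSE_FLOOR))
    pulses[[j]] <- data.frame(offset_secs = offs, apex = amp)
    extents[j] <- max(offs + tail_secs)
  }

  if (spec$n_tasks > 0) {
    starts <- place_tasks(spec, extents, shift_secs)
  } else {
    starts <- numeric(0)
  }

  apex_rows <- list()
  for (j in seq_len(spec$n_tasks)) {
    p <- pulses[[j]]
    for (q in seq_len(nrow(p))) {
      t0 <- starts[j] + p$offset_secs[q]
      a <- p$apex[q]
      if (a < PULSE_FLOOR) next
      i0 <- as.integer(ceiling(t0 / iv)) + 1L          # first sample at/after t0
      if (i0 > n) next
      L <- as.integer(floor(tau * log(a / PULSE_FLOOR) / iv))
      ii <- max(1L, i0):min(i0 + L, n)
      tt <- (ii - 1L) * iv
      contrib <- a * exp(-(tt - t0) / tau)
      contrib[contrib < PULSE_FLOOR] <- 0
      x[ii] <- x[ii] + contrib
    }
    apex_rows[[j]] <- data.frame(task_id = j,
                                 time_secs = starts[j] + p$offset_secs,
                                 apex_ppm = p$apex)
  }
  if (!is.null(spec$quantize_to)) {
    x <- round(x / spec$quantize_to) * spec$quantize_to
  }

  series <- new_gas_series(ts, x, iv,
                           meta = list(source = "synthetic",
                                       scenario_seed = spec$seed))
  validate_series(series)

  # realized task windows: positive samples within each nominal window
  win_rows <- list()
  for (j in seq_len(spec$n_tasks)) {
    lo <- max(1L, as.integer(floor(starts[j] / iv)) + 1L)
    hi <- min(n, as.integer(ceiling((starts[j] + extents[j]) / iv)) + 1L)
    pos <- which(x[lo:hi] > 0)
    if (length(pos) == 0) next
    s <- lo + pos[1] - 1L
    e <- lo + pos[length(pos)] - 1L
    win_rows[[length(win_rows) + 1L]] <-
      data.frame(task_id = j, start_index = s, end_index = e,
                 start_secs = (s - 1L) * iv, end_secs = (e - 1L) * iv)
  }
  task_windows <- if (length(win_rows)) {
    do.call(rbind, win_rows)
  } else {
    data.frame(task_id = integer(0), start_index = integer(0),
               end_index = integer(0), start_secs = numeric(0),
               end_secs = numeric(0))
  }

  elements <- oracle_elements(series, params)
  list(
    series = series,
    truth = list(
      task_windows = task_windows,
      peak_apexes = if (length(apex_rows)) do.call(rbind, apex_rows) else
        data.frame(task_id = integer(0), time_secs = numeric(0),
                   apex_ppm = numeric(0)),
      elements = elements,
      index = oracle_index(elements),
      n_tasks_nominal = spec$n_tasks,
      n_tasks_realized = nrow(task_windows)
    )
  )
}

place_tasks <- function(spec, extents, shift_secs) {
  n_tasks <- spec$n_tasks
  margin <- spec$task_gap / 2
  if (!is.null(spec$task_start_times)) {
    starts <- spec$task_start_times
    if (length(starts) != n_tasks) {
      h2s_error("task_start_times length must equal n_tasks", "h2s_parse_error")
    }
    if (n_tasks > 1) {
      gaps <- starts[-1] - (starts[-n_tasks] + extents[-n_tasks])
      if (any(gaps < spec$task_gap)) {
        h2s_error("infeasible spec: task windows overlap after accounting for the separation guard",
                  "h2s_parse_error")
      }
    }
    if (starts[n_tasks] + extents[n_tasks] > shift_secs) {
      h2s_error("infeasible spec: tasks extend past the end of the shift",
                "h2s_parse_error")
    }
    return(starts)
  }
  required <- sum(extents) + (n_tasks - 1) * spec$task_gap + 2 * margin
  slack <- shift_secs - required
  if (slack < 0) {
    h2s_error(sprintf(
      "infeasible spec: %d task(s) need %.0f s plus guards but the shift has %.0f s",
      n_tasks, sum(extents), shift_secs), "h2s_parse_error")
  }
  u <- stats::runif(n_tasks + 1)
  extra <- slack * u / sum(u)
  starts <- numeric(n_tasks)
  pos <- margin + extra[1]
  for (j in seq_len(n_tasks)) {
    starts[j] <- pos
    pos <- pos + extents[j] + spec$task_gap + extra[j + 1]
  }
  starts
}
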