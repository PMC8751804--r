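test_that("durations accumulate per band with the half-open boundary at 5 ppm", {
  expect_equal(accumulate_durations(make_series(numeric(2880))),
               c(dur01 = 0, dur5 = 0))
  x <- c(rep(0.4, 12), rep(8.0, 3), numeric(30))
  expect_equal(accumulate_durations(make_series(x)),
               c(dur01 = 2.0, dur5 = 0.5))
  s <- make_series(c(5.0, 5.1, 0, 0), interval = 60)
  expect_equal(accumulate_durations(s), c(dur01 = 1.0, dur5 = 1.0))
})

test_that("the index equation reproduces hand-evaluated fixtures", {
  expect_equal(compute_index(index_elements()), 0)
  expect_equal(
    compute_index(index_elements(c01 = 1, c5 = 1, dur01 = 2.0, dur5 = 0.5,
                                 max_ppm = 8.0)),
    0.1 + 0.2 + 0 + 5 + 2.5 + 0 + 8.0, tolerance = 0)
  expect_equal(
    compute_index(index_elements(c10 = 1, dur5 = 1.0, max_ppm = 12.0)),
    10 + 5 + 12, tolerance = 0)
})

test_that("the index decomposes into the seven weighted terms bit-exactly", {
  for (rep in 1:10) {
    sim <- generate_shift(scenario_spec(n_tasks = sample(1:4, 1),
                                        seed = 9000 + rep))
    report <- analyze_shift(sim$series)
    e <- report$elements
    w <- index_weights()
    expect_identical(report$index,
                     e$c01 * w[["c01"]] + e$dur01 * w[["dur01"]] +
                       e$c1 * w[["c1"]] + e$c5 * w[["c5"]] +
                       e$dur5 * w[["dur5"]] + e$c10 * w[["c10"]] +
                       e$max_ppm * w[["max"]])
  }
})

test_that("TWA arithmetic: dose over reference vs dose over measured time", {
  z <- compute_twa(make_series(numeric(480), interval = 60))
  expect_equal(z$twa_8h, 0)
  expect_equal(z$mean_measured, 0)

  x <- c(rep(0.1, 30), numeric(210))        # 4 h at 60-s logging
  tw <- compute_twa(make_series(x, interval = 60))
  expect_equal(tw$mean_measured, 0.0125)
  expect_equal(tw$twa_8h, 0.00625)

  const <- compute_twa(make_series(rep(1, 480), interval = 60))  # exactly 8 h
  expect_equal(const$twa_8h, 1.0)
  expect_equal(const$mean_measured, 1.0)

  expect_error(compute_twa(make_series(c(0, 0)), reference_hours = 0),
               class = "h2s_parse_error")
})

test_that("TWA scales linearly but the index does not", {
  sim <- generate_shift(scenario_spec(n_tasks = 3, quantize_to = NULL,
                                      seed = 9100))
  s <- sim$series
  base <- analyze_shift(s)
  for (c_scale in c(0.5, 3)) {
    scaled <- s
    scaled$readings <- s$readings * c_scale
    got <- analyze_shift(scaled)
    expect_equal(got$twa_8h, base$twa_8h * c_scale)
    expect_equal(got$mean_measured, base$mean_measured * c_scale)
  }
  # a fixture crossing the 5-ppm band shows the index is not homogeneous:
  x <- c(numeric(20), 4, numeric(20))
  s1 <- make_series(x)
  s2 <- make_series(2 * x)
  i1 <- analyze_shift(s1)$index   # c1 peak, dur01
  i2 <- analyze_shift(s2)$index   # becomes a c5 peak with dur5
  expect_gt(i2, 2 * i1)
})

test_that("exposed-period summaries match closed-form lognormal arithmetic", {
  s <- make_series(c(0.1, 1.0, 10.0, 0, 0))
  ex <- exposed_summary(s)
  expect_equal(ex$median, 1.0)
  expect_equal(ex$gm, 1.0)
  expect_equal(ex$gsd, 10.0)

  one <- exposed_summary(make_series(c(0, 0.7, 0)))
  expect_equal(one$median, 0.7)
  expect_equal(one$gm, 0.7)
  expect_true(is.na(one$gsd))

  flat <- exposed_summary(make_series(rep(2, 10)))
  expect_equal(flat$gm, 2.0)
  expect_equal(flat$gsd, 1.0)

  none <- exposed_summary(make_series(numeric(5)))
  expect_equal(none$n_exposed, 0L)
  expect_true(is.na(none$gm))
})

test_that("an unexposed shift reports index 0, TWA 0, no tasks", {
  report <- analyze_shift(make_series(numeric(2880)))
  expect_identical(report$index, 0)
  expect_equal(report$twa_8h, 0)
  expect_equal(report$n_tasks, 0L)
  expect_equal(report$n_exposed, 0L)
})

test_that("the single-spike shift composes to index 5 + 5/6 + 8", {
  report <- analyze_shift(single_spike_shift())
  expect_equal(report$n_tasks, 1L)
  e <- report$elements
  expect_identical(elements_list(e),
                   list(c01 = 0L, c1 = 0L, c5 = 1L, c10 = 0L,
                        dur01 = 0, dur5 = 10 / 60, max_ppm = 8.0))
  expect_equal(report$index, 5 + (10 / 60) * 5 + 8.0)
})

test_that("index 0, TWA 0 and zero positive readings coincide", {
  for (rep in 1:10) {
    sim <- generate_shift(scenario_spec(n_tasks = sample(0:3, 1),
                                        seed = 9200 + rep))
    report <- analyze_shift(sim$series)
    zero_index <- report$index == 0
    expect_equal(zero_index, report$twa_8h == 0)
    expect_equal(zero_index, report$n_exposed == 0)
    expect_equal(zero_index, report$elements$max_ppm == 0)
  }
})

test_that("report invariants hold on generated shifts", {
  for (rep in 1:10) {
    sim <- generate_shift(scenario_spec(n_tasks = sample(1:4, 1),
                                        seed = 9300 + rep))
    report <- analyze_shift(sim$series)
    e <- report$elements
    expect_gte(report$index, 0)
    # any positive reading implies >= 1 task implies >= 1 peak
    expect_equal(e$max_ppm > 0, (e$c01 + e$c1 + e$c5 + e$c10) >= 1)
    if (e$dur5 > 0) expect_gt(e$max_ppm, 5.0)
    if (report$measurement_duration_h <= 8) {
      expect_lte(report$twa_8h, report$mean_measured + 1e-12)
    }
  }
})
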