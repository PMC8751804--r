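test_that("read_series parses a minimal well-formed log", {
  ts <- SHIFT_START + c(0, 10, 20)
  f <- write_csv_fixture(ts, c("0.0", "0.5", "0.0"))
  s <- read_series(f)
  expect_s3_class(s, "gas_series")
  expect_length(s, 3)
  expect_equal(s$interval, 10)
  expect_equal(s$readings, c(0, 0.5, 0))
  expect_equal(s$timestamps, ts)
  expect_equal(s$meta$source, f)
})

test_that("concentration column is auto-detected by a 'ppm' header", {
  ts <- SHIFT_START + seq(0, by = 2, length.out = 100)
  x <- round(runif(100, 0, 3), 1)
  f <- write_csv_fixture(ts, x, header = c("Logged time", "H2S (ppm)"))
  s <- read_series(f)
  expect_length(s, 100)
  expect_equal(s$interval, 2)
  expect_equal(s$readings, x)
})

test_that("explicit column_map beats header detection and bad maps error", {
  ts <- SHIFT_START + c(0, 10, 20)
  f <- write_csv_fixture(ts, c(1, 2, 3),
                         header = c("timestamp", "other"))
  s <- read_series(f, column_map = list(reading = "other"))
  expect_equal(s$readings, c(1, 2, 3))
  expect_error(read_series(f, column_map = list(reading = "nope")),
               class = "h2s_parse_error")
})

test_that("semicolon-separated exports are auto-detected", {
  ts <- SHIFT_START + seq(0, 40, by = 10)
  f <- write_csv_fixture(ts, c(0, 1, 2, 1, 0), sep = ";")
  s <- read_series(f)
  expect_equal(s$readings, c(0, 1, 2, 1, 0))
})

test_that("irregular gaps beyond tolerance are a classed validation error", {
  ts <- SHIFT_START + c(0, 10, 20, 80, 90, 100)  # one 60-s gap
  f <- write_csv_fixture(ts, rep(0, 6))
  err <- expect_error(read_series(f), class = "h2s_interval_error")
  expect_match(conditionMessage(err), "60")   # names the offending gap
  expect_match(conditionMessage(err), "row")  # and the position
})

test_that("malformed timestamps and negative readings are distinct errors", {
  f1 <- tempfile(fileext = ".csv")
  writeLines(c("timestamp,h2s_ppm",
               "2014-03-10T07:00:00,0.0",
               "not-a-time,0.5",
               "2014-03-10T07:00:20,0.0"), f1)
  err <- expect_error(read_series(f1), class = "h2s_parse_error")
  expect_match(conditionMessage(err), "row 2")

  ts <- SHIFT_START + c(0, 10, 20)
  f2 <- write_csv_fixture(ts, c(0, -0.1, 0))
  expect_error(read_series(f2), class = "h2s_negative_error")
})

test_that("fill_short_gaps interpolates short gaps and leaves long ones", {
  ts <- SHIFT_START + c(0, 10, 30, 40)  # one sample missing at +20
  gappy <- h2sindex:::new_gas_series(ts, c(0, 1, 3, 0), 10)
  filled <- fill_short_gaps(gappy, max_gap = 30)
  expect_length(filled, 5)
  expect_equal(filled$readings, c(0, 1, 2, 3, 0))
  expect_equal(as.numeric(diff(filled$timestamps), units = "secs"),
               rep(10, 4))
  expect_equal(filled$meta$filled_gaps$n_inserted, 1L)
  expect_silent(validate_series(filled))

  # identity on a gap-free series
  ok <- make_series(c(0, 1, 0))
  expect_identical(fill_short_gaps(ok, 30)[c("timestamps", "readings")],
                   ok[c("timestamps", "readings")])

  # a 10-sample hole exceeds the bound and survives untouched
  ts2 <- SHIFT_START + c(seq(0, 40, 10), seq(150, 190, 10))
  long_gap <- h2sindex:::new_gas_series(ts2, rep(0, 10), 10)
  same <- fill_short_gaps(long_gap, max_gap = 30)
  expect_length(same, 10)
  expect_error(validate_series(same), class = "h2s_interval_error")
})

test_that("read_series can repair short gaps on ingest", {
  ts <- SHIFT_START + c(0, 10, 30, 40)
  f <- write_csv_fixture(ts, c(0, 1, 3, 0))
  expect_error(read_series(f), class = "h2s_interval_error")
  s <- read_series(f, fill_max_gap = 30)
  expect_length(s, 5)
  expect_equal(s$readings[3], 2)
})

test_that("series round-trip through CSV is the identity up to 4 decimals", {
  set.seed(101)
  for (interval in c(2, 10, 60)) {
    x <- ifelse(runif(200) < 0.8, 0, round(rlnorm(200, log(1.8), log(9.3)), 1))
    s <- make_series(x, interval = interval)
    f <- tempfile(fileext = ".csv")
    write_series(s, f)
    back <- read_series(f)
    expect_equal(back$readings, round(s$readings, 4))
    expect_equal(back$timestamps, s$timestamps)
    expect_equal(back$interval, s$interval)
  }
})

test_that("JSON report round-trip reproduces every numeric field exactly", {
  rep0 <- analyze_shift(make_series(numeric(100)))
  f <- tempfile(fileext = ".json")
  write_report(rep0, f)
  back <- read_report(f)
  expect_identical(back$index, rep0$index)
  expect_identical(back$index, 0)

  ts <- SHIFT_START + seq(0, by = 10, length.out = 240)
  x <- numeric(240)
  x[30:41] <- 0.4   # 12 samples in (0,5]
  x[100:102] <- 8.0 # 3 samples above 5
  rep1 <- analyze_shift(gas_series(ts, x))
  f1 <- tempfile(fileext = ".json")
  write_report(rep1, f1)
  back1 <- read_report(f1)
  for (field in c("index", "twa_8h", "mean_measured", "measurement_duration_h",
                  "exposed_median", "exposed_gm", "exposed_gsd")) {
    expect_identical(back1[[field]], rep1[[field]], label = field)
  }
  expect_identical(elements_list(back1$elements), elements_list(rep1$elements))
  expect_identical(back1$task_durations_min, rep1$task_durations_min)
})

test_that("a batch of reports serializes to one CSV row each plus header", {
  reports <- lapply(list(numeric(50), c(numeric(20), 2, numeric(29)),
                         c(numeric(10), 7, numeric(39))),
                    function(x) analyze_shift(make_series(x)))
  f <- tempfile(fileext = ".csv")
  write_batch_csv(reports, f)
  expect_length(readLines(f), 4L)
  got <- utils::read.csv(f)
  expect_equal(nrow(got), 3L)
  expect_equal(got$index, sort(sapply(reports, `[[`, "index"),
                               decreasing = TRUE))
})
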