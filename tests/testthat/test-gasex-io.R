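test_that("breath CSVs round-trip through write/read", {
  s <- make_session_series(hr = 120)
  s$ve <- 20 + s$t / 1000
  f <- withr::local_tempfile(fileext = ".csv")
  write_breath_csv(s, f)
  s2 <- read_breath_csv(f)
  expect_equal(s2$t, s$t)
  expect_equal(s2$vo2, s$vo2)
  expect_equal(s2$ve, s$ve)
  expect_equal(s2$hr, s$hr)
  expect_equal(s2$phase, s$phase)
})

test_that("a minimal two-row file parses and unit conversion applies", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,vo2_l_min,phase", "0,0.3,rest", "3,0.31,rest"), f)
  s <- read_breath_csv(f)
  expect_s3_class(s, "breath_series")
  expect_equal(nrow(s), 2)

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,vo2,phase", "0,300,rest", "3,310,rest"), f2)
  s2 <- read_breath_csv(f2, column_map = list(t = "t", vo2 = "vo2"),
                        vo2_unit = "ml_min")
  expect_equal(s2$vo2, c(0.3, 0.31))

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,vo2,phase", "0,3.5,rest", "3,3.6,rest"), f3)
  s3 <- read_breath_csv(f3, column_map = list(t = "t", vo2 = "vo2"),
                        vo2_unit = "ml_kg_min", body_mass = 80)
  expect_equal(s3$vo2, c(0.28, 0.288))
})

test_that("malformed breath files raise the contracted errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,phase", "0,rest"), f)
  expect_error(read_breath_csv(f), class = "ergo_format_error")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,vo2_l_min,phase", "10,0.3,rest", "5,0.3,rest"), f2)
  expect_error(read_breath_csv(f2), regexp = "row 2",
               class = "ergo_validation_error")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,vo2_l_min,phase", "0,0.3,warmup"), f3)
  expect_error(read_breath_csv(f3), regexp = "phase",
               class = "ergo_validation_error")

  expect_error(read_breath_csv(tempfile()), class = "ergo_format_error")
})

test_that("series validation rejects out-of-order phases and bad channels", {
  expect_error(
    breath_series(tibble::tibble(t = c(0, 3, 6),
                                 vo2 = 0.3,
                                 phase = c("exercise", "rest", "rest"))),
    class = "ergo_validation_error"
  )
  expect_error(
    breath_series(tibble::tibble(t = c(0, 3, 6),
                                 vo2 = 0.3,
                                 phase = c("rest", "exercise", "rest"))),
    class = "ergo_validation_error"
  )
  expect_error(
    breath_series(tibble::tibble(t = 0, vo2 = -0.1, phase = "rest")),
    class = "ergo_validation_error"
  )
  expect_error(
    breath_series(tibble::tibble(t = 0, vo2 = 0.3, hr = 300, phase = "rest")),
    class = "ergo_validation_error"
  )
})

test_that("windowed averages of a constant channel return the constant", {
  s <- make_session_series(hr = 120)
  bins <- bin_phase_averages(s, "hr", window = 300)
  ex <- bins[bins$phase == "exercise", ]
  expect_equal(nrow(ex), 6)
  expect_equal(ex$mean_value, rep(120, 6))
  expect_equal(ex$window_start, 300 + 300 * (0:5))
})

test_that("windowed averages equal brute-force means of covered breaths", {
  t <- seq(0, 597, by = 3)
  s <- breath_series(tibble::tibble(t = t, vo2 = t, phase = "rest"))
  bins <- bin_phase_averages(s, "vo2", window = 300)
  expect_equal(nrow(bins), 2)
  expect_equal(bins$mean_value[1], mean(t[t >= 0 & t < 300]))
  expect_equal(bins$mean_value[2], mean(t[t >= 300 & t < 600]))
})

test_that("windows longer than the data raise an error", {
  s <- breath_series(tibble::tibble(t = seq(0, 27, 3), vo2 = 0.3,
                                    phase = "rest"))
  expect_error(bin_phase_averages(s, "vo2", window = 300),
               class = "ergo_validation_error")
  expect_error(bin_phase_averages(s, "vo2", window = -1),
               class = "ergo_validation_error")
})

test_that("baseline VO2 is the mean of the final rest window", {
  s <- make_session_series(rest_vo2 = 0.3)
  expect_equal(baseline_vo2(s), 0.3)

  # seeded noisy rest trace: baseline equals the enumerated mean
  set.seed(42)
  t <- seq(0, 297, by = 3)
  vo2 <- 0.3 + rnorm(length(t), 0, 0.03)
  s2 <- breath_series(tibble::tibble(t = t, vo2 = vo2, phase = "rest"))
  covered <- t >= 300 - 120 & t < 300  # rest ends at last breath + interval
  expect_equal(baseline_vo2(s2, window = 120), mean(vo2[covered]))
})

test_that("baseline VO2 requires a long-enough rest and ignores exercise", {
  short <- breath_series(tibble::tibble(t = seq(0, 57, 3), vo2 = 0.3,
                                        phase = "rest"))
  expect_error(baseline_vo2(short, window = 120),
               class = "ergo_validation_error")

  rest <- tibble::tibble(t = seq(0, 297, 3), vo2 = 0.3, phase = "rest")
  s1 <- breath_series(rest)
  with_ex <- dplyr::bind_rows(
    rest, tibble::tibble(t = seq(300, 597, 3), vo2 = 1.2, phase = "exercise")
  )
  s2 <- breath_series(with_ex)
  expect_equal(baseline_vo2(s1), baseline_vo2(s2))
})
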