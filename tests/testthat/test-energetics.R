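test_that("lactate profiles validate their sample structure", {
  expect_s3_class(make_lactate_profile(1.0, posts = c(2, 2.5, 2.2, 2.0)),
                  "lactate_profile")
  # no pre sample
  expect_error(
    lactate_profile(tibble::tibble(label = "post0", t_min = 30, conc = 2)),
    class = "ergo_validation_error"
  )
  # no post sample
  expect_error(
    lactate_profile(tibble::tibble(label = c("pre", "rec15"),
                                   t_min = c(-5, 45), conc = c(1, 1.2))),
    class = "ergo_validation_error"
  )
  expect_error(
    lactate_profile(tibble::tibble(label = c("pre", "peak"),
                                   t_min = c(-5, 30), conc = c(1, 2))),
    class = "ergo_validation_error"
  )
  expect_error(
    lactate_profile(tibble::tibble(label = c("pre", "post0"),
                                   t_min = c(-5, 30), conc = c(-1, 2))),
    class = "ergo_validation_error"
  )
})

test_that("lactate CSVs round-trip through write/read", {
  p <- make_lactate_profile(1.17, posts = c(2.89, 2.5, 2.2, 2.0),
                            ex15 = 2.94, rec15 = 1.55)
  f <- withr::local_tempfile(fileext = ".csv")
  write_lactate_csv(p, f)
  p2 <- read_lactate_csv(f)
  expect_equal(p2$label, p$label)
  expect_equal(p2$conc, p$conc)
  expect_equal(p2$t_min, p$t_min)
})

test_that("aerobic volume matches closed-form areas", {
  # rectangle: constant 1.0 L/min for 30 min above a 0.3 baseline
  s <- make_session_series(ex_vo2 = 1.0)
  expect_equal(aerobic_volume(s, baseline = 0.3), 21, tolerance = 1e-6)

  # triangle: linear ramp 0.3 -> 1.3 over 30 min, baseline 0.3
  t <- seq(0, 1800, by = 3)
  ramp <- breath_series(tibble::tibble(t = t, vo2 = 0.3 + t / 1800,
                                       phase = "exercise"))
  expect_equal(aerobic_volume(ramp, baseline = 0.3), 15, tolerance = 1e-6)
})

test_that("aerobic volume flags sub-baseline exercise and short phases", {
  s <- make_session_series(ex_vo2 = 0.25)
  expect_warning(v <- aerobic_volume(s, baseline = 0.3), regexp = "negative")
  expect_lt(v, 0)
  expect_true(isTRUE(attr(v, "negative")))

  short <- make_session_series(ex_s = 600)
  expect_error(aerobic_volume(short, baseline = 0.3, duration_min = 30),
               class = "ergo_validation_error")
  expect_error(aerobic_volume(make_session_series(), baseline = -0.1),
               class = "ergo_validation_error")
})

test_that("net lactate is peak post-exercise minus pre", {
  p <- make_lactate_profile(1.17, posts = c(2.89, 2.5, 2.2, 2.0))
  expect_equal(net_lactate(p), 1.72)

  flat <- make_lactate_profile(1.3, posts = rep(1.3, 4))
  expect_equal(net_lactate(flat), 0)

  # enumeration oracle over random profiles; ex15 never enters the peak
  set.seed(11)
  for (i in 1:20) {
    pre <- runif(1, 0.5, 2)
    posts <- runif(4, 0.5, 4)
    p <- make_lactate_profile(pre, posts = posts, ex15 = 10)
    expect_equal(net_lactate(p), max(posts) - pre)
  }
})

test_that("lactic volume applies the 3 mL/kg per mmol/L equivalence", {
  expect_equal(lactic_volume(1.0, 1.0), 0.003)
  expect_equal(lactic_volume(1.72, 82.8), 1.72 * 3 * 82.8 / 1000)
  expect_warning(v <- lactic_volume(-0.2, 80), regexp = "clamped")
  expect_equal(as.numeric(v), 0)
  expect_true(isTRUE(attr(v, "clamped")))
  expect_equal(lactic_volume(-0.2, 80, clamp_negative = FALSE), -0.048)
  expect_error(lactic_volume(1, 0), class = "ergo_validation_error")
})

test_that("oxygen volumes convert to energy by the caloric equivalent", {
  expect_equal(o2_volume_to_energy(1), 20.92)
  expect_equal(o2_volume_to_energy(0), 0)
  expect_equal(o2_volume_to_energy(21), 439.32)
  expect_error(o2_volume_to_energy(1, caloric_equiv = 0),
               class = "ergo_validation_error")
})

test_that("partition_session agrees with its stage operations", {
  pop <- make_population(1, seed = 3)
  eff <- condition_effects()
  s <- simulate_breath_series(pop, eff, "LIE", seed = 3)
  prof <- simulate_lactate_profile(pop, eff, "LIE", seed = 3)
  p <- partition_session(s, prof, pop$body_mass)

  base <- baseline_vo2(s, window = 120)
  expect_equal(p$baseline_vo2_l_min, base)
  expect_equal(p$aerobic_l, as.numeric(aerobic_volume(s, base)))
  fit <- fit_off_kinetics(s, seed = 1L)
  expect_equal(p$alactic_l, alactic_volume(fit))
  expect_equal(p$net_lactate_mmol_l, net_lactate(prof))
  expect_equal(p$lactic_l, as.numeric(lactic_volume(net_lactate(prof),
                                                    pop$body_mass)))
  expect_equal(p$total_kj, p$total_l * 20.92)
})

test_that("partition_session identifies the failing stage", {
  pop <- make_population(1, seed = 4)
  s <- simulate_breath_series(pop, condition_effects(), "LIE", seed = 4)
  expect_error(partition_session(s, NULL, pop$body_mass),
               regexp = "lactate", class = "ergo_stage_error")
  prof <- simulate_lactate_profile(pop, condition_effects(), "LIE", seed = 4)
  expect_error(partition_session(s, prof, body_mass = -1),
               class = "ergo_stage_error")
})

test_that("a zero-noise session recovers the generator ground truth", {
  eff0 <- condition_effects(noise_vo2 = 0, noise_la = 0, noise_hr = 0,
                            noise_ve = 0)
  # pin td in the identifiable regime (above the breath interval)
  pop <- make_population(2, seed = 9,
                         params = list(td = c(0.1, 0.002, 0.09, 0.11)))
  for (cond in c("LIE", "LIE_BFR")) {
    s <- simulate_breath_series(pop[1, ], eff0, cond, seed = 9)
    prof <- simulate_lactate_profile(pop[1, ], eff0, cond, seed = 9)
    p <- partition_session(s, prof, pop$body_mass[1])
    ts <- attr(s, "truth"); tp <- attr(prof, "truth")
    expect_lt(abs(p$aerobic_l / ts$aerobic_l - 1), 0.01)
    expect_lt(abs(p$alactic_l / ts$alactic_l - 1), 0.01)
    expect_lt(abs(p$lactic_l / tp$lactic_l - 1), 0.01)
  }
})

test_that("partitions conserve the total and scale with body mass", {
  pop <- make_population(1, seed = 5)
  eff <- condition_effects()
  s <- simulate_breath_series(pop, eff, "LIE_BFR", seed = 5)
  prof <- simulate_lactate_profile(pop, eff, "LIE_BFR", seed = 5)
  p1 <- partition_session(s, prof, pop$body_mass)
  expect_identical(p1$total_l, p1$aerobic_l + p1$alactic_l + p1$lactic_l)

  p2 <- partition_session(s, prof, pop$body_mass * 2)
  expect_equal(p2$lactic_l, 2 * p1$lactic_l)
  expect_equal(p2$aerobic_l, p1$aerobic_l)
  expect_equal(p2$alactic_l, p1$alactic_l)
})

test_that("components respond monotonically to their inputs", {
  pop <- make_population(1, seed = 6)
  s <- simulate_breath_series(pop, condition_effects(), "LIE", seed = 6)
  base <- baseline_vo2(s)
  up <- s
  up$vo2 <- up$vo2 + 0.1
  expect_gt(as.numeric(aerobic_volume(up, base)),
            as.numeric(aerobic_volume(s, base)))
  expect_gt(lactic_volume(1.5, 80), lactic_volume(1.0, 80))
})
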