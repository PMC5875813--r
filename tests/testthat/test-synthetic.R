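test_that("population draws are reproducible and respect their moments", {
  p1 <- make_population(12, seed = 42)
  p2 <- make_population(12, seed = 42)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 12)
  p3 <- make_population(12, seed = 43)
  expect_false(identical(p1, p3))

  big <- make_population(1e4, seed = 1)
  expect_lt(abs(mean(big$body_mass) / 82.8 - 1), 0.01)
  expect_lt(abs(mean(big$vo2max) / 33.4 - 1), 0.01)
  expect_true(all(big$vo2max >= 20 & big$vo2max <= 60))
  expect_true(all(big$td >= 0))

  expect_error(make_population(0), class = "ergo_validation_error")
  expect_error(make_population(3, params = list(body_mass = c(80, -1, 50, 120))),
               class = "ergo_validation_error")
})

test_that("simulated recovery reproduces the subject's off-kinetics exactly", {
  eff0 <- condition_effects(noise_vo2 = 0, noise_la = 0, noise_hr = 0,
                            noise_ve = 0)
  # keep td above the breath interval so the pre-delay plateau is observed
  # (below it, td and A1 trade off exactly on noiseless data)
  pop <- make_population(2, seed = 21,
                         params = list(td = c(0.1, 0.002, 0.09, 0.11)))
  s <- simulate_breath_series(pop[2, ], eff0, "LIE", seed = 21)
  tr <- attr(s, "truth")

  # recovery tail sits on the subject baseline (residual decay ~ A1*e^(-9/tau1))
  tail_vo2 <- s$vo2[s$phase == "recovery" & s$t > max(s$t) - 60]
  decay_bound <- tr$A1 * exp(-9 / tr$tau1) / tr$rest_vo2
  expect_lt(abs(mean(tail_vo2) / tr$rest_vo2 - 1), 0.001 + decay_bound)

  fit <- fit_off_kinetics(s)
  expect_lt(abs(fit$A1 / tr$A1 - 1), 1e-6)
  expect_lt(abs(fit$tau1 / tr$tau1 - 1), 1e-6)
  expect_lt(abs(fit$td - tr$td), 1e-5)
  expect_lt(abs(fit$baseline / tr$rest_vo2 - 1), 1e-6)
})

test_that("zero-noise conditions differ only through the effect channels", {
  eff0 <- condition_effects(noise_vo2 = 0, noise_la = 0, noise_hr = 0,
                            noise_ve = 0)
  pop <- make_population(1, seed = 33)
  a <- simulate_breath_series(pop, eff0, "LIE", seed = 33)
  b <- simulate_breath_series(pop, eff0, "LIE_BFR", seed = 33)
  expect_identical(a$t, b$t)
  expect_identical(a$phase, b$phase)
  # rest and recovery VO2 identical; exercise shifted upward by d_vo2_ss
  expect_identical(a$vo2[a$phase != "exercise"], b$vo2[b$phase != "exercise"])
  ex <- a$phase == "exercise"
  expect_true(all(b$vo2[ex] >= a$vo2[ex]))
  expect_true(all(b$hr[ex] > a$hr[ex]))
  expect_true(all(b$ve[ex] > a$ve[ex]))
})

test_that("lactate profiles hit the configured net rise and calibration", {
  eff0 <- condition_effects(noise_la = 0, d_la_peak = 0)
  pop <- make_population(1, seed = 2)
  p <- simulate_lactate_profile(pop, eff0, "LIE_BFR", seed = 2)
  expect_equal(net_lactate(p), eff0$la_rise)

  flat <- condition_effects(noise_la = 0, d_la_peak = 0, la_rise = 0)
  p0 <- simulate_lactate_profile(pop, flat, "LIE", seed = 2)
  expect_equal(net_lactate(p0), 0)
  expect_equal(sd(p0$conc), 0)

  # ensemble: BFR peaks exceed LIE peaks, and group means stay within one
  # SD of the printed reference values (pre ~1.32/1.17, peak ~1.97/2.89)
  eff <- condition_effects()
  peaks <- list(LIE = numeric(0), LIE_BFR = numeric(0))
  pres <- list(LIE = numeric(0), LIE_BFR = numeric(0))
  for (seed in 1:100) {
    subj <- make_population(1, seed = seed)
    for (cond in c("LIE", "LIE_BFR")) {
      pr <- simulate_lactate_profile(subj, eff, cond, seed = seed)
      peaks[[cond]] <- c(peaks[[cond]],
                         max(pr$conc[pr$label %in% c("post0", "post3",
                                                     "post5", "post7")]))
      pres[[cond]] <- c(pres[[cond]], pr$conc[pr$label == "pre"])
    }
  }
  expect_gt(mean(peaks$LIE_BFR), mean(peaks$LIE))
  expect_lt(abs(mean(pres$LIE) - 1.32), 0.55)
  expect_lt(abs(mean(pres$LIE_BFR) - 1.17), 0.44)
  expect_lt(abs(mean(peaks$LIE) - 1.97), 1.18)
  expect_lt(abs(mean(peaks$LIE_BFR) - 2.89), 1.49)
})

test_that("trial datasets are deterministic and fully enumerated on disk", {
  t1 <- simulate_crossover_trial(n = 3, seed = 14)
  t2 <- simulate_crossover_trial(n = 3, seed = 14)
  expect_identical(t1$sessions$series, t2$sessions$series)
  expect_identical(t1$sessions$profile, t2$sessions$profile)
  expect_equal(nrow(t1$sessions), 6)
  expect_true(all(table(t1$sessions$subject_id) == 2))

  dir <- withr::local_tempdir()
  write_trial_dataset(t1, dir)
  files <- list.files(dir)
  expect_equal(sum(grepl("_breath\\.csv$", files)), 6)
  expect_equal(sum(grepl("_lactate\\.csv$", files)), 6)
  expect_true(all(c("subjects.csv", "manifest.json") %in% files))

  # manifests differ between seeds only in the recorded seed
  t3 <- simulate_crossover_trial(n = 3, seed = 15)
  dir3 <- withr::local_tempdir()
  write_trial_dataset(t3, dir3)
  m1 <- jsonlite::read_json(file.path(dir, "manifest.json"))
  m3 <- jsonlite::read_json(file.path(dir3, "manifest.json"))
  expect_equal(m1$seed, 14)
  expect_equal(m3$seed, 15)
  m1$seed <- m3$seed <- NULL
  expect_identical(m1, m3)

  # a written breath file round-trips into the same series
  row <- t1$sessions[1, ]
  back <- read_breath_csv(file.path(dir, paste0(row$subject_id, "_",
                                                row$condition, "_breath.csv")))
  expect_equal(back$vo2, row$series[[1]]$vo2, tolerance = 1e-9)
})

test_that("trials rebuilt from a zero-noise generator match ground truth", {
  eff0 <- condition_effects(noise_vo2 = 0, noise_la = 0, noise_hr = 0,
                            noise_ve = 0)
  trial <- simulate_crossover_trial(
    n = 2, effects = eff0, seed = 27,
    population_params = list(td = c(0.1, 0.002, 0.09, 0.11))
  )
  parts <- partition_trial(trial)
  expect_equal(nrow(parts), 4)
  joined <- dplyr::left_join(parts, trial$sessions,
                             by = c("subject_id", "condition"))
  expect_true(all(abs(joined$aerobic_l / joined$aerobic_l_true - 1) < 0.01))
  expect_true(all(abs(joined$alactic_l / joined$alactic_l_true - 1) < 0.01))
  expect_true(all(abs(joined$lactic_l / joined$lactic_l_true - 1) < 0.01))
  expect_true(all(abs(joined$total_l / joined$total_l_true - 1) < 0.01))
})

test_that("condition comparisons report the configured effect directions", {
  trial <- simulate_crossover_trial(n = 6, seed = 31)
  parts <- partition_trial(trial)
  cmp <- compare_conditions(parts)
  expect_setequal(cmp$component,
                  c("aerobic_l", "alactic_l", "lactic_l", "total_l",
                    "total_kj"))
  expect_gt(cmp$mean_diff[cmp$component == "lactic_l"], 0)
  expect_gt(cmp$mean_diff[cmp$component == "total_l"], 0)
})
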