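#' Default population moments for the synthetic cohort
#'
#' Mean, SD and truncation bounds of each subject-level parameter drawn by
#' [make_population()]. Body mass (82.8 +/- 12.6 kg) and maximal oxygen
#' uptake (33.4 +/- 4.6 mL·kg^-1·min^-1) reproduce the moments of the
#' sedentary young-adult cohort the pipeline targets; the remaining fields
#' use values typical of that population: resting V-dot-O2 near 3.5
#' mL·kg^-1·min^-1 (0.30 L·min^-1), on-kinetics time constant about 30 s,
#' fast-EPOC amplitude 0.6 L·min^-1 with a 45 s time constant and a short
#' time delay, resting lactate near 1.25 mmol·L^-1 and resting heart rate
#' near 68 beats·min^-1. Parameters are drawn independently.
#'
#' @return Named list of `c(mean, sd, lower, upper)` vectors.
#' @export
population_defaults <- function() {
  list(
    body_mass = c(82.8, 12.6, 50, 130),
    vo2max = c(33.4, 4.6, 20, 60),
    age = c(24.5, 4.0, 18, 30),
    rest_vo2 = c(0.30, 0.04, 0.18, 0.45),
    tau_on = c(0.50, 0.08, 0.25, 1.0),
    A1 = c(0.60, 0.10, 0.30, 1.20),
    tau1 = c(0.75, 0.12, 0.40, 1.50),
    td = c(0.08, 0.04, 0.0, 0.30),
    la_pre = c(1.25, 0.45, 0.40, 3.00),
    hr_rest = c(68, 7, 50, 90)
  )
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Deterministic substream seed: one global seed expands to per-subject /
# per-condition / per-channel streams so any piece is reproducible alone.
substream_seed <- function(seed, ...) {
  key <- paste(..., collapse = "/")
  cp <- utf8ToInt(key)
  h <- sum(cp * ((seq_along(cp) - 1) %% 31 + 1)) %% 1e6
  as.integer((as.numeric(seed) %% 2147483647 * 2971 + h * 131 + 17) %% 2147483647)
}

#' Draw a synthetic subject population
#'
#' Each parameter is drawn from an independent truncated normal with the
#' moments in `params` (see [population_defaults()]), reproducibly under
#' `seed`.
#'
#' @param n Number of subjects (>= 1).
#' @param seed Integer seed.
#' @param params Population moments; entries override
#'   [population_defaults()].
#' @return Tibble with one row per subject (`subject_id` plus one column per
#'   parameter).
#' @export
make_population <- function(n, seed = 1L, params = list()) {
  if (!is.numeric(n) || n < 1) {
    abort("`n` must be >= 1.", class = "ergo_validation_error")
  }
  n <- as.integer(n)
  p <- utils::modifyList(population_defaults(), params)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (length(v) != 4 || v[2] < 0 || v[4] <= v[3]) {
      abort(paste0("Invalid moments for `", nm,
                   "`: need c(mean, sd, lower, upper) with sd >= 0, upper > lower."),
            class = "ergo_validation_error")
    }
  }
  set.seed(substream_seed(seed, "population"))
  out <- tibble::tibble(subject_id = sprintf("S%02d", seq_len(n)))
  for (nm in names(p)) {
    v <- p[[nm]]
    out[[nm]] <- rtruncnorm(n, v[1], v[2], v[3], v[4])
  }
  out
}

#' Condition-effect and noise configuration for the simulator
#'
#' Defaults are calibrated to the blood-flow-restriction crossover the
#' pipeline is built for: under BFR the peak-lactate response gains about
#' 1.0 mmol·L^-1 on top of a 0.7 mmol·L^-1 exercise rise (so the
#' no-restriction session peaks near 2.0 mmol·L^-1 and the restricted one
#' near 2.9), steady-state exercise V-dot-O2 gains 0.05 L·min^-1, heart
#' rate 8 beats·min^-1 and ventilation 4 L·min^-1; the alactic component is
#' deliberately unaffected. Breath noise is 0.03 L·min^-1 (SD per breath)
#' and lactate sampling noise 0.12 mmol·L^-1, consistent with a
#' test-retest typical error of about 0.07 mmol·L^-1.
#'
#' @param d_la_peak Additive BFR shift in the peak-lactate rise, mmol·L^-1.
#' @param d_vo2_ss BFR shift in exercise steady-state V-dot-O2, L·min^-1.
#' @param d_hr BFR shift in exercise heart rate, beats·min^-1.
#' @param d_ve BFR shift in exercise ventilation, L·min^-1.
#' @param la_rise Exercise rise of lactate above the pre value without BFR,
#'   mmol·L^-1.
#' @param noise_vo2 Breath-level Gaussian V-dot-O2 noise SD, L·min^-1.
#' @param noise_la Lactate sample noise SD, mmol·L^-1.
#' @param noise_hr Breath-level heart-rate noise SD, beats·min^-1.
#' @param noise_ve Breath-level ventilation noise SD, L·min^-1.
#' @return Named list of class `condition_effects`.
#' @export
condition_effects <- function(d_la_peak = 1.0, d_vo2_ss = 0.05, d_hr = 8,
                              d_ve = 4, la_rise = 0.7, noise_vo2 = 0.03,
                              noise_la = 0.12, noise_hr = 2, noise_ve = 1) {
  for (v in c(noise_vo2, noise_la, noise_hr, noise_ve)) {
    if (v < 0) abort("Noise SDs must be >= 0.", class = "ergo_validation_error")
  }
  structure(
    list(d_la_peak = d_la_peak, d_vo2_ss = d_vo2_ss, d_hr = d_hr,
         d_ve = d_ve, la_rise = la_rise, noise_vo2 = noise_vo2,
         noise_la = noise_la, noise_hr = noise_hr, noise_ve = noise_ve),
    class = "condition_effects"
  )
}

as_subject_params <- function(subject) {
  if (is.data.frame(subject)) {
    stopifnot(nrow(subject) == 1)
    subject <- as.list(subject)
  }
  subject
}

# O2 cost of cycling above rest: 10.8 mL O2 per minute per watt.
cycling_economy_ml_min_w <- 10.8

# Power prescribed at 40% of maximal oxygen uptake for one subject, W.
power_at_40pct <- function(subject) {
  s <- as_subject_params(subject)
  vo2_target_l <- 0.4 * s$vo2max * s$body_mass / 1000
  max((vo2_target_l - s$rest_vo2) * 1000 / cycling_economy_ml_min_w, 10)
}

#' Simulate one breath-by-breath session
#'
#' Forward model of a constant-load session: seated rest at the subject's
#' resting V-dot-O2, a mono-exponential on-transient (time constant
#' `tau_on`) to the exercise steady state, and a mono-exponential recovery
#' decay with the subject's off-kinetics parameters (`A1`, `tau1`, `td`),
#' clocked from the last exercise breath. The exercise steady state is 40%
#' of the subject's maximal oxygen uptake, plus the configured shift under
#' blood-flow restriction. Heart rate and ventilation follow analogous
#' on/off kinetics with their own condition shifts. Breaths arrive every
#' `interval` seconds with uniform jitter, and every channel carries
#' Gaussian noise.
#'
#' Breath timing is seeded per subject only (identical across conditions),
#' while channel noise is seeded per subject and condition, so zero-noise
#' series of the two conditions differ only through the configured effect
#' channels.
#'
#' @param subject One row of [make_population()] (or an equivalent list).
#' @param effects A [condition_effects()] configuration.
#' @param condition `"LIE"` or `"LIE_BFR"`.
#' @param seed Integer trial seed.
#' @param durations Named vector of phase durations in seconds
#'   (`rest`, `exercise`, `recovery`).
#' @param interval Mean breath interval, seconds.
#' @param jitter Half-width of the uniform breath-interval jitter, seconds.
#' @return A [breath_series()]; the generating ground truth (steady state,
#'   power, kinetic parameters, true aerobic volume) is attached as
#'   attribute `truth`.
#' @export
simulate_breath_series <- function(subject, effects = condition_effects(),
                                   condition = c("LIE", "LIE_BFR"),
                                   seed = 1L,
                                   durations = c(rest = 300, exercise = 1800,
                                                 recovery = 600),
                                   interval = 3, jitter = 0.5) {
  condition <- match.arg(condition)
  s <- as_subject_params(subject)
  stopifnot(all(c("rest", "exercise", "recovery") %in% names(durations)),
            all(durations > 0))
  bfr <- condition == "LIE_BFR"
  total <- sum(durations)
  rest_end <- unname(durations["rest"])
  ex_end <- rest_end + unname(durations["exercise"])

  set.seed(substream_seed(seed, s$subject_id, "times"))
  n_max <- ceiling(total / max(interval - jitter, 0.5)) + 8
  gaps <- runif(n_max, interval - jitter, interval + jitter)
  t <- cumsum(gaps)
  t <- t[t < total]
  phase <- ifelse(t < rest_end, "rest",
                  ifelse(t < ex_end, "exercise", "recovery"))

  ss_vo2 <- 0.4 * s$vo2max * s$body_mass / 1000 + if (bfr) effects$d_vo2_ss else 0
  power_w <- power_at_40pct(s)
  t_end_ex <- max(t[phase == "exercise"])

  vo2 <- numeric(length(t))
  vo2[phase == "rest"] <- s$rest_vo2
  te <- (t[phase == "exercise"] - rest_end) / 60
  vo2[phase == "exercise"] <-
    s$rest_vo2 + (ss_vo2 - s$rest_vo2) * (1 - exp(-te / s$tau_on))
  tr <- (t[phase == "recovery"] - t_end_ex) / 60
  vo2[phase == "recovery"] <-
    s$rest_vo2 + s$A1 * off_kinetics_shape(tr, s$tau1, s$td)

  hr_ss <- s$hr_rest + 42 + if (bfr) effects$d_hr else 0
  hr <- numeric(length(t))
  hr[phase == "rest"] <- s$hr_rest
  hr[phase == "exercise"] <- s$hr_rest + (hr_ss - s$hr_rest) * (1 - exp(-te / 0.75))
  hr[phase == "recovery"] <- s$hr_rest + (hr_ss - s$hr_rest) * exp(-tr / 1.5)

  ve_rest <- 9
  ve_ss <- 24 + if (bfr) effects$d_ve else 0
  ve <- numeric(length(t))
  ve[phase == "rest"] <- ve_rest
  ve[phase == "exercise"] <- ve_rest + (ve_ss - ve_rest) * (1 - exp(-te / 0.75))
  ve[phase == "recovery"] <- ve_rest + (ve_ss - ve_rest) * exp(-tr / 1.0)

  vco2 <- 0.85 * vo2

  set.seed(substream_seed(seed, s$subject_id, condition, "noise"))
  vo2 <- pmax(vo2 + rnorm(length(t), 0, effects$noise_vo2), 0)
  vco2 <- pmax(vco2 + rnorm(length(t), 0, effects$noise_vo2), 0)
  hr <- pmin(pmax(hr + rnorm(length(t), 0, effects$noise_hr), 20), 250)
  ve <- pmax(ve + rnorm(length(t), 0, effects$noise_ve), 0)

  series <- breath_series(
    tibble::tibble(t = t, vo2 = vo2, vco2 = vco2, ve = ve, hr = hr,
                   phase = phase),
    subject_id = s$subject_id, condition = condition
  )
  ex_min <- unname(durations["exercise"]) / 60
  attr(series, "truth") <- list(
    rest_vo2 = s$rest_vo2, ss_vo2 = ss_vo2, power_w = power_w,
    A1 = s$A1, tau1 = s$tau1, td = s$td, tau_on = s$tau_on,
    t_end_exercise_s = t_end_ex,
    aerobic_l = (ss_vo2 - s$rest_vo2) *
      (ex_min - s$tau_on * (1 - exp(-ex_min / s$tau_on))),
    alactic_l = s$A1 * s$tau1
  )
  series
}

#' Simulate one session's lactate profile
#'
#' Samples the canonical schedule (pre, 15 min of exercise, 0/3/5/7 min
#' post-exercise, 15 min of recovery) from a fixed response shape: the
#' concentration rises from the subject's resting value by `la_rise`
#' (plus `d_la_peak` under blood-flow restriction), peaks in the first
#' minutes after exercise, and decays back towards the pre value by 15 min
#' of recovery. Gaussian sampling noise (`noise_la`) is added and
#' concentrations are floored at zero.
#'
#' @inheritParams simulate_breath_series
#' @param exercise_min Exercise duration in minutes (anchors the sample
#'   times).
#' @return A [lactate_profile()] with the generating truth (`la_pre`,
#'   effective rise, true lactic O2 volume) attached as attribute `truth`.
#' @export
simulate_lactate_profile <- function(subject, effects = condition_effects(),
                                     condition = c("LIE", "LIE_BFR"),
                                     seed = 1L, exercise_min = 30) {
  condition <- match.arg(condition)
  s <- as_subject_params(subject)
  bfr <- condition == "LIE_BFR"
  rise <- effects$la_rise + if (bfr) effects$d_la_peak else 0

  shape <- c(pre = 0, ex15 = 1.0, post0 = 0.95, post3 = 1.0,
             post5 = 0.85, post7 = 0.7, rec15 = 0.2)
  t_min <- c(pre = -5, ex15 = 15, post0 = exercise_min,
             post3 = exercise_min + 3, post5 = exercise_min + 5,
             post7 = exercise_min + 7, rec15 = exercise_min + 15)

  set.seed(substream_seed(seed, s$subject_id, condition, "lactate"))
  conc <- pmax(s$la_pre + shape * rise +
                 rnorm(length(shape), 0, effects$noise_la), 0)

  profile <- lactate_profile(
    tibble::tibble(label = names(shape), t_min = unname(t_min),
                   conc = unname(conc)),
    subject_id = s$subject_id, condition = condition
  )
  attr(profile, "truth") <- list(
    la_pre = s$la_pre, la_rise = rise,
    lactic_l = rise * 3 * s$body_mass / 1000
  )
  profile
}

#' Simulate a complete crossover trial
#'
#' Draws a subject population and generates, for every subject, one breath
#' series and one lactate profile under each condition (with and without
#' blood-flow restriction), together with per-session ground-truth energy
#' components. Optionally writes the dataset to a directory of CSV files
#' with a JSON manifest (see [write_trial_dataset()]).
#'
#' @param n Number of subjects (>= 2).
#' @param effects A [condition_effects()] configuration.
#' @param seed Integer trial seed; all randomness derives from it.
#' @param durations Phase durations in seconds.
#' @param population_params Overrides for [population_defaults()].
#' @param out_dir Optional output directory for the CSV dataset.
#' @return An object of class `crossover_trial`: a list with `subjects`,
#'   `sessions` (tibble with list-columns `series` and `profile` and the
#'   per-session truth columns `aerobic_l_true`, `alactic_l_true`,
#'   `lactic_l_true`, `total_l_true`), `effects`, `durations` and `seed`.
#' @export
simulate_crossover_trial <- function(n = 12, effects = condition_effects(),
                                     seed = 1L,
                                     durations = c(rest = 300,
                                                   exercise = 1800,
                                                   recovery = 600),
                                     population_params = list(),
                                     out_dir = NULL) {
  if (!is.numeric(n) || n < 2) {
    abort("`n` must be >= 2 for a crossover trial.",
          class = "ergo_validation_error")
  }
  subjects <- make_population(n, seed = seed, params = population_params)
  grid <- tidyr::expand_grid(subject_id = subjects$subject_id,
                             condition = c("LIE", "LIE_BFR"))
  ex_min <- unname(durations["exercise"]) / 60

  rows <- purrr::pmap(grid, function(subject_id, condition) {
    subj <- subjects[subjects$subject_id == subject_id, ]
    series <- simulate_breath_series(subj, effects, condition, seed = seed,
                                     durations = durations)
    profile <- simulate_lactate_profile(subj, effects, condition, seed = seed,
                                        exercise_min = ex_min)
    ts <- attr(series, "truth")
    tp <- attr(profile, "truth")
    tibble::tibble(
      subject_id = subject_id, condition = condition,
      body_mass = subj$body_mass,
      series = list(series), profile = list(profile),
      aerobic_l_true = ts$aerobic_l, alactic_l_true = ts$alactic_l,
      lactic_l_true = tp$lactic_l,
      total_l_true = ts$aerobic_l + ts$alactic_l + tp$lactic_l
    )
  })

  trial <- structure(
    list(subjects = subjects, sessions = dplyr::bind_rows(rows),
         effects = effects, durations = durations, seed = as.integer(seed)),
    class = "crossover_trial"
  )
  if (!is.null(out_dir)) write_trial_dataset(trial, out_dir)
  trial
}

#' Write a crossover trial to a directory of CSV files
#'
#' One breath CSV and one lactate CSV per subject x condition, a
#' `subjects.csv` with the subject parameters, and a `manifest.json`
#' recording the seed, cohort size, effect configuration, phase durations
#' and file list.
#'
#' @param trial A `crossover_trial`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_dataset <- function(trial, dir) {
  stopifnot(inherits(trial, "crossover_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (i in seq_len(nrow(trial$sessions))) {
    row <- trial$sessions[i, ]
    stem <- paste0(row$subject_id, "_", row$condition)
    bf <- paste0(stem, "_breath.csv")
    lf <- paste0(stem, "_lactate.csv")
    write_breath_csv(row$series[[1]], file.path(dir, bf))
    write_lactate_csv(row$profile[[1]], file.path(dir, lf))
    files <- c(files, bf, lf)
  }
  readr::write_csv(trial$subjects, file.path(dir, "subjects.csv"),
                   progress = FALSE)
  manifest <- list(
    generator = "bfrenergetics::simulate_crossover_trial",
    seed = trial$seed,
    n_subjects = nrow(trial$subjects),
    effects = unclass(trial$effects),
    durations_s = as.list(trial$durations),
    files = c(files, "subjects.csv")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.crossover_trial <- function(x, ...) {
  cat("<crossover_trial> ", nrow(x$subjects), " subjects x 2 conditions | seed ",
      x$seed, "\n", sep = "")
  cat("  effects: d_la_peak", x$effects$d_la_peak,
      "| d_vo2_ss", x$effects$d_vo2_ss,
      "| d_hr", x$effects$d_hr, "| d_ve", x$effects$d_ve, "\n")
  invisible(x)
}

#' Partition every session of a crossover trial
#'
#' Runs [partition_session()] on each subject x condition session of a
#' simulated (or assembled) trial.
#'
#' @param trial A `crossover_trial`.
#' @param ... Passed on to [partition_session()].
#' @return Tibble of class `trial_partitions`: one row per session with
#'   `subject_id`, `condition` and all energy-partition columns.
#' @export
partition_trial <- function(trial, ...) {
  stopifnot(inherits(trial, "crossover_trial"))
  rows <- purrr::pmap(
    list(trial$sessions$series, trial$sessions$profile,
         trial$sessions$body_mass),
    function(series, profile, body_mass, ...) {
      p <- partition_session(series, profile, body_mass,
                             seed = trial$seed, ...)
      dplyr::bind_cols(
        tibble::tibble(subject_id = attr(series, "subject_id"),
                       condition = attr(series, "condition")),
        tibble::as_tibble(p)
      )
    },
    ...
  )
  out <- dplyr::bind_rows(rows)
  class(out) <- c("trial_partitions", class(tibble::tibble()))
  out
}

#' Compare conditions component-wise with paired t-tests
#'
#' Pairs each subject's two sessions and applies [paired_t()] to every
#' energy component (the crossover contrast of interest: does restriction
#' change the component?).
#'
#' @param partitions A `trial_partitions` tibble from [partition_trial()].
#' @param components Components to compare.
#' @return Tibble: `component`, `mean_lie`, `mean_bfr`, `mean_diff`
#'   (BFR - LIE), `t`, `df`, `p`.
#' @export
compare_conditions <- function(partitions,
                               components = c("aerobic_l", "alactic_l",
                                              "lactic_l", "total_l",
                                              "total_kj")) {
  stopifnot(is.data.frame(partitions))
  purrr::map_dfr(components, function(comp) {
    wide <- tidyr::pivot_wider(
      partitions[, c("subject_id", "condition", comp)],
      names_from = "condition", values_from = dplyr::all_of(comp)
    )
    res <- paired_t(wide, a = "LIE", b = "LIE_BFR")
    tibble::tibble(
      component = comp,
      mean_lie = mean(wide$LIE), mean_bfr = mean(wide$LIE_BFR),
      mean_diff = res$mean_diff, t = res$t, df = res$df, p = res$p
    )
  })
}
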