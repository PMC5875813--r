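#' Construct a blood-lactate profile
#'
#' A lactate profile holds the labelled earlobe samples of one session:
#' `pre` (before exercise), `ex15` (15 min into exercise), `post0`, `post3`,
#' `post5`, `post7` (immediately and 3/5/7 min after exercise) and `rec15`
#' (15 min of recovery). A valid profile has exactly one `pre` sample and at
#' least one post-exercise sample; concentrations are non-negative.
#'
#' @param samples Data frame with columns `label`, `t_min` (minutes relative
#'   to exercise start) and `conc` (mmol·L^-1).
#' @param subject_id Optional subject identifier.
#' @param condition `"LIE"`, `"LIE_BFR"` or `NA`.
#' @return A tibble of class `lactate_profile`.
#' @export
lactate_profile <- function(samples, subject_id = NA_character_,
                            condition = NA_character_) {
  if (!is.data.frame(samples)) {
    abort("`samples` must be a data frame.", class = "ergo_format_error")
  }
  required <- c("label", "t_min", "conc")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ergo_format_error")
  }
  x <- tibble::as_tibble(samples)[, required]
  x$label <- as.character(x$label)
  x$t_min <- as.numeric(x$t_min)
  x$conc <- as.numeric(x$conc)
  unknown <- setdiff(unique(x$label), lactate_labels())
  if (length(unknown) > 0) {
    abort(paste0("Unknown lactate sample label(s): ",
                 paste(unknown, collapse = ", ")),
          class = "ergo_validation_error")
  }
  if (sum(x$label == "pre") != 1) {
    abort("A lactate profile must contain exactly one `pre` sample.",
          class = "ergo_validation_error")
  }
  if (!any(x$label %in% post_labels())) {
    abort("A lactate profile needs at least one post-exercise sample (post0/post3/post5/post7).",
          class = "ergo_validation_error")
  }
  if (any(!is.na(x$conc) & x$conc < 0)) {
    abort("Lactate concentrations must be non-negative.",
          class = "ergo_validation_error")
  }
  structure(
    x,
    subject_id = subject_id,
    condition = if (is.na(condition)) NA_character_ else match.arg(condition, c("LIE", "LIE_BFR")),
    class = c("lactate_profile", class(tibble::tibble()))
  )
}

lactate_labels <- function() c("pre", "ex15", "post0", "post3", "post5", "post7", "rec15")
post_labels <- function() c("post0", "post3", "post5", "post7")

#' Read a lactate sample CSV
#'
#' Dialect: comma-separated with header `label, time_min, lactate_mmol_l`,
#' labels from `pre, ex15, post0, post3, post5, post7, rec15`.
#'
#' @param path CSV file path.
#' @inheritParams lactate_profile
#' @return A [lactate_profile()].
#' @export
read_lactate_csv <- function(path, subject_id = NA_character_,
                             condition = NA_character_) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "ergo_format_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("label", "time_min", "lactate_mmol_l")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", "), " in ", path),
          class = "ergo_format_error")
  }
  lactate_profile(
    tibble::tibble(label = raw$label, t_min = raw$time_min,
                   conc = raw$lactate_mmol_l),
    subject_id = subject_id, condition = condition
  )
}

#' Write a lactate profile to CSV
#' @param profile A [lactate_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lactate_csv <- function(profile, path) {
  stopifnot(inherits(profile, "lactate_profile"))
  readr::write_csv(
    tibble::tibble(label = profile$label, time_min = profile$t_min,
                   lactate_mmol_l = profile$conc),
    path, progress = FALSE
  )
  invisible(path)
}

#' Aerobic oxygen volume of an exercise bout
#'
#' Area under the exercise-phase V-dot-O2 curve over the declared exercise
#' duration, minus the resting baseline times that duration. Breaths are
#' linearly interpolated to a 1-second grid anchored at the start of the
#' exercise phase before trapezoidal integration (breath-by-breath data are
#' unevenly spaced), with constant extrapolation at the grid edges.
#'
#' @param series A [breath_series()] with an exercise phase covering
#'   `duration_min` (a slack of `span_tol_s` seconds is allowed for breath
#'   jitter).
#' @param baseline Resting baseline V-dot-O2 in L·min^-1 (see
#'   [baseline_vo2()]).
#' @param duration_min Exercise duration integrated, minutes (default 30).
#' @param span_tol_s Tolerance on the required exercise span, seconds.
#' @return Aerobic oxygen volume in L. A negative value (exercise V-dot-O2
#'   below baseline throughout) is returned as-is with a warning and the
#'   attribute `negative = TRUE`.
#' @export
aerobic_volume <- function(series, baseline, duration_min = 30,
                           span_tol_s = 10) {
  stopifnot(inherits(series, "breath_series"))
  if (!is.numeric(baseline) || baseline < 0) {
    abort("`baseline` must be a non-negative V-dot-O2 in L/min.",
          class = "ergo_validation_error")
  }
  ex <- series[series$phase == "exercise" & !is.na(series$vo2), ]
  if (nrow(ex) < 2) {
    abort("Series has no usable exercise phase.", class = "ergo_validation_error")
  }
  dur_s <- duration_min * 60
  span <- max(ex$t) - min(ex$t)
  if (span < dur_s - span_tol_s) {
    abort(
      paste0("Exercise phase spans ", round(span, 1),
             " s, shorter than the requested duration (", dur_s, " s)."),
      class = "ergo_validation_error"
    )
  }
  grid <- seq(0, dur_s, by = 1)
  vo2_grid <- approx(ex$t - min(ex$t), ex$vo2, xout = grid, rule = 2)$y
  # trapezoid on the unit grid; L/min integrated over seconds -> /60 for L
  auc_l <- (sum(vo2_grid) - (vo2_grid[1] + vo2_grid[length(vo2_grid)]) / 2) / 60
  out <- auc_l - baseline * duration_min
  if (out < 0) {
    warn("Aerobic volume is negative: exercise V-dot-O2 lies below the baseline.")
    attr(out, "negative") <- TRUE
  }
  out
}

#' Net blood-lactate accumulation
#'
#' Peak post-exercise concentration (maximum over the `post0/post3/post5/
#' post7` samples) minus the pre-exercise concentration. The 15-min exercise
#' sample is retained in profiles for reporting but does not enter the peak.
#'
#' @param profile A [lactate_profile()].
#' @return Net accumulation in mmol·L^-1 (may be negative).
#' @export
net_lactate <- function(profile) {
  stopifnot(inherits(profile, "lactate_profile"))
  posts <- profile$conc[profile$label %in% post_labels() & !is.na(profile$conc)]
  if (length(posts) == 0) {
    abort("No post-exercise lactate samples available.",
          class = "ergo_validation_error")
  }
  pre <- profile$conc[profile$label == "pre"]
  max(posts) - pre
}

#' Anaerobic lactic oxygen volume from net lactate
#'
#' Converts net lactate accumulation to an oxygen equivalent using the
#' standard constant of 3 mL O2 per kg body mass per mmol·L^-1 of net
#' lactate. A negative net accumulation is clamped to zero with a warning
#' (set `clamp_negative = FALSE` to propagate the negative volume instead).
#'
#' @param delta_la Net lactate accumulation, mmol·L^-1.
#' @param body_mass Body mass in kg (> 0).
#' @param o2_equiv_ml_kg O2 equivalent per unit net lactate,
#'   mL·kg^-1·(mmol·L^-1)^-1; default 3.
#' @param clamp_negative Clamp negative net lactate to zero? Default `TRUE`.
#' @return Lactic oxygen volume in L. Carries attribute `clamped = TRUE`
#'   when the clamp was applied.
#' @export
#' @examples
#' lactic_volume(1.72, 82.8)  # 0.427 L
lactic_volume <- function(delta_la, body_mass, o2_equiv_ml_kg = 3,
                          clamp_negative = TRUE) {
  if (!is.numeric(body_mass) || body_mass <= 0) {
    abort("`body_mass` must be positive (kg).", class = "ergo_validation_error")
  }
  clamped <- FALSE
  if (delta_la < 0 && clamp_negative) {
    warn(paste0("Negative net lactate (", round(delta_la, 3),
                " mmol/L) clamped to 0 for the lactic volume."))
    delta_la <- 0
    clamped <- TRUE
  }
  out <- delta_la * o2_equiv_ml_kg * body_mass / 1000
  if (clamped) attr(out, "clamped") <- TRUE
  out
}

#' Convert an oxygen volume to energy
#'
#' @param volume Oxygen volume in L.
#' @param caloric_equiv Caloric equivalent in kJ per L O2; default 20.92
#'   (about 5 kcal per L O2, the conventional constant for
#'   moderate-intensity exercise).
#' @return Energy in kJ.
#' @export
o2_volume_to_energy <- function(volume, caloric_equiv = 20.92) {
  if (!is.numeric(caloric_equiv) || caloric_equiv <= 0) {
    abort("`caloric_equiv` must be positive (kJ/L).",
          class = "ergo_validation_error")
  }
  volume * caloric_equiv
}

#' Partition a session into energy-system contributions
#'
#' Orchestrates the full per-session analysis: resting baseline V-dot-O2
#' ([baseline_vo2()]), aerobic volume as the exercise V-dot-O2 area above
#' baseline ([aerobic_volume()]), anaerobic alactic volume from the
#' off-kinetics fit of the recovery phase ([fit_off_kinetics()] then
#' [alactic_volume()]), and anaerobic lactic volume from net lactate
#' accumulation ([net_lactate()] then [lactic_volume()]). Total oxygen cost
#' is the exact sum of the three components, converted to kJ with the
#' caloric equivalent.
#'
#' @param series A [breath_series()] with rest, exercise and recovery phases.
#' @param profile A [lactate_profile()] for the same session.
#' @param body_mass Body mass in kg.
#' @param duration_min Exercise duration integrated for the aerobic
#'   component, minutes (default 30).
#' @param baseline_window Rest-baseline averaging window, seconds
#'   (default 120).
#' @param fit_window_min Recovery window for the kinetics fit, minutes
#'   (default 10).
#' @param caloric_equiv kJ per L O2 (default 20.92).
#' @param clamp_negative_lactate Clamp negative net lactate to zero?
#' @param seed Seed forwarded to [fit_off_kinetics()].
#' @return A one-row tibble of class `energy_partition` with columns
#'   `aerobic_l`, `alactic_l`, `lactic_l`, `total_l`, `total_kj`,
#'   `body_mass`, `caloric_equiv`, `net_lactate_mmol_l` and
#'   `baseline_vo2_l_min`; the `recovery_fit` and a structured log of
#'   intermediate values are attached as attributes `fit` and `log`.
#' @export
partition_session <- function(series, profile, body_mass,
                              duration_min = 30, baseline_window = 120,
                              fit_window_min = 10, caloric_equiv = 20.92,
                              clamp_negative_lactate = TRUE, seed = 1L) {
  if (!inherits(series, "breath_series")) {
    abort("gas-exchange stage: `series` must be a breath_series.",
          class = "ergo_stage_error")
  }
  if (is.null(profile) || !inherits(profile, "lactate_profile")) {
    abort("lactate stage: `profile` must be a lactate_profile (missing or wrong type).",
          class = "ergo_stage_error")
  }
  if (!is.numeric(body_mass) || body_mass <= 0) {
    abort("lactate stage: `body_mass` must be positive (kg).",
          class = "ergo_stage_error")
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0(name, " stage failed: ", conditionMessage(e)),
            class = "ergo_stage_error", parent = e)
    })
  }

  baseline <- stage("baseline", baseline_vo2(series, window = baseline_window))
  aerobic <- stage("aerobic",
                   aerobic_volume(series, baseline, duration_min = duration_min))
  fit <- stage("kinetics",
               fit_off_kinetics(series, fit_window_min = fit_window_min,
                                seed = seed))
  alactic <- alactic_volume(fit)
  dla <- stage("lactate", net_lactate(profile))
  lactic <- stage("lactate",
                  lactic_volume(dla, body_mass,
                                clamp_negative = clamp_negative_lactate))

  aerobic_l <- as.numeric(aerobic)
  lactic_l <- as.numeric(lactic)
  total_l <- aerobic_l + alactic + lactic_l
  out <- tibble::tibble(
    aerobic_l = aerobic_l,
    alactic_l = alactic,
    lactic_l = lactic_l,
    total_l = total_l,
    total_kj = o2_volume_to_energy(total_l, caloric_equiv),
    body_mass = body_mass,
    caloric_equiv = caloric_equiv,
    net_lactate_mmol_l = dla,
    baseline_vo2_l_min = baseline
  )
  attr(out, "fit") <- fit
  attr(out, "flags") <- list(
    negative_aerobic = isTRUE(attr(aerobic, "negative")),
    lactate_clamped = isTRUE(attr(lactic, "clamped"))
  )
  attr(out, "log") <- list(
    subject_id = attr(series, "subject_id"),
    condition = attr(series, "condition"),
    baseline_vo2_l_min = baseline,
    recovery_fit = list(baseline = fit$baseline, A1 = fit$A1,
                        tau1 = fit$tau1, td = fit$td, rss = fit$rss),
    net_lactate_mmol_l = dla,
    duration_min = duration_min,
    baseline_window_s = baseline_window,
    fit_window_min = fit_window_min
  )
  class(out) <- c("energy_partition", class(tibble::tibble()))
  out
}

#' @export
print.energy_partition <- function(x, ...) {
  cat("<energy_partition>\n")
  cat(sprintf("  aerobic  %8.3f L O2\n", x$aerobic_l))
  cat(sprintf("  alactic  %8.3f L O2\n", x$alactic_l))
  cat(sprintf("  lactic   %8.3f L O2\n", x$lactic_l))
  cat(sprintf("  total    %8.3f L O2 = %.1f kJ (at %.2f kJ/L)\n",
              x$total_l, x$total_kj, x$caloric_equiv))
  cat(sprintf("  baseline %.3f L/min | net lactate %.2f mmol/L | mass %.1f kg\n",
              x$baseline_vo2_l_min, x$net_lactate_mmol_l, x$body_mass))
  flags <- attr(x, "flags")
  if (isTRUE(flags$negative_aerobic)) cat("  [flag] negative aerobic volume\n")
  if (isTRUE(flags$lactate_clamped)) cat("  [flag] negative net lactate clamped\n")
  invisible(x)
}
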