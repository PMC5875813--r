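#' Build the incremental cycling test protocol
#'
#' Stage table for the graded exercise test: minute 1 at `start_w` (50 W),
#' increments of `step1_w` (15 W) per minute until a stage reaches
#' `switch_w` (200 W), then increments of `step2_w` (10 W) per minute until
#' `max_minutes`.
#'
#' @param max_minutes Number of 1-minute stages (>= 1).
#' @param start_w Initial load, W.
#' @param step1_w Increment per minute below the switch load, W.
#' @param switch_w Load at which the increment changes, W.
#' @param step2_w Increment per minute at and above the switch load, W.
#' @return Tibble with columns `minute_index`, `power`.
#' @export
#' @examples
#' build_protocol(13)
build_protocol <- function(max_minutes, start_w = 50, step1_w = 15,
                           switch_w = 200, step2_w = 10) {
  if (!is.numeric(max_minutes) || max_minutes < 1) {
    abort("`max_minutes` must be >= 1.", class = "ergo_validation_error")
  }
  max_minutes <- as.integer(max_minutes)
  power <- numeric(max_minutes)
  power[1] <- start_w
  for (m in seq_len(max_minutes)[-1]) {
    step <- if (power[m - 1] >= switch_w) step2_w else step1_w
    power[m] <- power[m - 1] + step
  }
  tibble::tibble(minute_index = seq_len(max_minutes), power = power)
}

#' Evaluate maximal-effort criteria for an incremental test
#'
#' A test is considered maximal when at least two of four criteria hold:
#' a plateau in oxygen uptake, a peak respiratory exchange ratio above 1.1,
#' a peak heart rate at or above 90% of the age-predicted maximum
#' (220 - age), and a rating of perceived exertion above 17 on the 6-20
#' scale (strictly greater). Missing inputs (`NA`/`NULL`) simply fail their
#' criterion; supplying no criterion input at all is an error.
#'
#' @param plateau Logical plateau flag (see [vo2_plateau()] for the delta
#'   rule used to derive it from stage means), or `NA`.
#' @param rer_max Peak respiratory exchange ratio, or `NA`.
#' @param hr_max Peak heart rate, beats·min^-1, or `NA`.
#' @param age Age in years (10-90); required when `hr_max` is given.
#' @param rpe_max Peak perceived exertion on the 6-20 Borg scale, or `NA`.
#' @return One-row tibble with logical columns `plateau`, `rer_gt_1_1`,
#'   `hr_ge_90pct_pred`, `rpe_gt_17`, the count `n_met` and `is_maximal`.
#' @export
#' @examples
#' maximality_criteria(plateau = FALSE, rer_max = 1.15, hr_max = 185,
#'                     age = 24, rpe_max = 15)
maximality_criteria <- function(plateau = NA, rer_max = NA, hr_max = NA,
                                age = NA, rpe_max = NA) {
  plateau <- plateau %||% NA
  rer_max <- rer_max %||% NA
  hr_max <- hr_max %||% NA
  rpe_max <- rpe_max %||% NA
  if (all(is.na(c(plateau, rer_max, hr_max, rpe_max)))) {
    abort("At least one maximality input must be provided.",
          class = "ergo_validation_error")
  }
  if (!is.na(hr_max)) {
    if (is.na(age) || age < 10 || age > 90) {
      abort("`age` in [10, 90] is required to evaluate the heart-rate criterion.",
            class = "ergo_validation_error")
    }
  }
  c_plateau <- isTRUE(as.logical(plateau))
  c_rer <- !is.na(rer_max) && rer_max > 1.1
  c_hr <- !is.na(hr_max) && hr_max >= 0.9 * (220 - age)
  c_rpe <- !is.na(rpe_max) && rpe_max > 17
  n_met <- sum(c_plateau, c_rer, c_hr, c_rpe)
  tibble::tibble(
    plateau = c_plateau, rer_gt_1_1 = c_rer, hr_ge_90pct_pred = c_hr,
    rpe_gt_17 = c_rpe, n_met = n_met, is_maximal = n_met >= 2
  )
}

#' Oxygen-uptake plateau by the delta rule
#'
#' Operational plateau criterion: the V-dot-O2 increase between the final
#' two completed stages is below `delta_ml_min` (default 150 mL·min^-1).
#'
#' @param stage_vo2_l_min Per-stage mean V-dot-O2 values in L·min^-1,
#'   in stage order (>= 2 stages).
#' @param delta_ml_min Plateau threshold, mL·min^-1.
#' @return Logical.
#' @export
vo2_plateau <- function(stage_vo2_l_min, delta_ml_min = 150) {
  if (length(stage_vo2_l_min) < 2) {
    abort("At least two stage means are needed to assess a plateau.",
          class = "ergo_validation_error")
  }
  n <- length(stage_vo2_l_min)
  (stage_vo2_l_min[n] - stage_vo2_l_min[n - 1]) * 1000 < delta_ml_min
}

#' Detect a ventilatory breakpoint by segmented regression
#'
#' Automated surrogate for the visual determination of the ventilatory
#' threshold (non-linear rise of VE/VO2) and respiratory compensation point
#' (non-linear rise of VE/VCO2): a continuous two-segment piecewise-linear
#' least-squares fit is computed for every candidate breakpoint on a grid of
#' interior predictor values, and the breakpoint minimising the residual sum
#' of squares is kept. The breakpoint is accepted (`found = TRUE`) when the
#' two-segment fit improves on the single straight line by an F-ratio test
#' (2 extra parameters) at level `alpha`; an essentially perfect single line
#' reports `found = FALSE`.
#'
#' @param x Ordered, strictly increasing predictor values (e.g. V-dot-O2 or
#'   power along the ramp); at least 8 points.
#' @param y Ventilatory-equivalent values at `x`.
#' @param kind `"VT"` or `"RCP"` (label only; the numerical procedure is
#'   identical).
#' @param alpha Significance level of the F-ratio gate (default 0.05).
#' @param fco2 Optional expired CO2 fraction values at `x`; for `kind =
#'   "RCP"` they add the confirmatory check that the fraction falls after
#'   the breakpoint (`fco2_confirms`), otherwise the check is skipped with
#'   `fco2_confirms = NA`.
#' @return One-row tibble: `kind`, `breakpoint` (x units), `found`,
#'   `f_stat`, `p_value`, `rss_line`, `rss_segmented`, `fco2_confirms`.
#' @export
detect_breakpoint <- function(x, y, kind = c("VT", "RCP"), alpha = 0.05,
                              fco2 = NULL) {
  kind <- match.arg(kind)
  n <- length(x)
  if (n < 8) {
    abort("At least 8 points are required for breakpoint detection.",
          class = "ergo_validation_error")
  }
  if (length(y) != n) {
    abort("`x` and `y` must have equal length.", class = "ergo_validation_error")
  }
  if (any(diff(x) <= 0)) {
    abort("`x` must be strictly increasing.", class = "ergo_validation_error")
  }

  X0 <- cbind(1, x)
  fit0 <- stats::lm.fit(X0, y)
  rss0 <- sum(fit0$residuals^2)
  ss_tot <- sum((y - mean(y))^2)

  candidates <- x[3:(n - 2)]
  best <- list(rss = Inf, bp = NA_real_, coef = NULL)
  for (cp in candidates) {
    X <- cbind(1, x, pmax(x - cp, 0))
    f <- stats::lm.fit(X, y)
    rss <- sum(f$residuals^2)
    if (rss < best$rss) best <- list(rss = rss, bp = cp, coef = f$coefficients)
  }

  if (rss0 <= 1e-10 * max(ss_tot, .Machine$double.eps)) {
    # data already a perfect straight line: nothing to detect
    found <- FALSE
    f_stat <- 0
    p_value <- 1
  } else {
    df_den <- n - 4
    f_stat <- ((rss0 - best$rss) / 2) / (best$rss / df_den)
    if (!is.finite(f_stat)) f_stat <- Inf  # zero residual segmented fit
    p_value <- pf(f_stat, 2, df_den, lower.tail = FALSE)
    found <- p_value <= alpha
  }

  fco2_confirms <- NA
  if (identical(kind, "RCP") && !is.null(fco2) && found) {
    after <- x > best$bp
    fco2_confirms <- sum(after) >= 2 &&
      mean(diff(fco2[after])) < 0
  }

  tibble::tibble(
    kind = kind,
    breakpoint = if (found) best$bp else NA_real_,
    found = found,
    f_stat = f_stat,
    p_value = p_value,
    rss_line = rss0,
    rss_segmented = best$rss,
    fco2_confirms = fco2_confirms
  )
}

#' Express an oxygen uptake as a percentage of maximum
#'
#' @param value V-dot-O2 in mL·kg^-1·min^-1.
#' @param vo2max Maximal oxygen uptake, same units (> 0).
#' @return `100 * value / vo2max`, rounded to one decimal.
#' @export
#' @examples
#' fraction_of_vo2max(20.4, 33.4)  # 61.1
fraction_of_vo2max <- function(value, vo2max) {
  if (!is.numeric(vo2max) || any(vo2max <= 0)) {
    abort("`vo2max` must be positive.", class = "ergo_validation_error")
  }
  round(100 * value / vo2max, 1)
}

#' Cuff-pressure prescription from arterial occlusion pressure
#'
#' Session cuff pressure as a fraction of the maximal (tibial) arterial
#' occlusion pressure, rounded to the nearest integer mmHg (cuff hardware
#' resolution). The conventional prescription for blood-flow-restricted
#' endurance exercise is 80% of the occlusion pressure.
#'
#' @param aop Arterial occlusion pressure, mmHg (> 0).
#' @param fraction Fraction of `aop` in \[0, 1\]; default 0.8.
#' @return One-row tibble with `aop`, `fraction`, `target` (mmHg, integer).
#' @export
#' @examples
#' occlusion_target(136, 0.8)  # target 109 mmHg
occlusion_target <- function(aop, fraction = 0.8) {
  if (!is.numeric(aop) || any(aop <= 0)) {
    abort("`aop` must be positive (mmHg).", class = "ergo_validation_error")
  }
  if (!is.numeric(fraction) || any(fraction < 0) || any(fraction > 1)) {
    abort("`fraction` must lie in [0, 1].", class = "ergo_validation_error")
  }
  tibble::tibble(aop = aop, fraction = fraction,
                 target = as.integer(round(fraction * aop)))
}
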