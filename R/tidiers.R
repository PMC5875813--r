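#' Tidy a recovery fit
#'
#' @param x A `recovery_fit` from [fit_off_kinetics()].
#' @param ... Unused.
#' @return Tibble with one row per model parameter (`term`, `estimate`,
#'   `unit`).
#' @exportS3Method generics::tidy
tidy.recovery_fit <- function(x, ...) {
  tibble::tibble(
    term = c("baseline", "A1", "tau1", "td"),
    estimate = c(x$baseline, x$A1, x$tau1, x$td),
    unit = c("L/min", "L/min", "min", "min")
  )
}

#' One-row fit summary of a recovery fit
#'
#' @inheritParams tidy.recovery_fit
#' @return Tibble with `rss`, `n_breaths`, `alactic_volume_l`,
#'   `fit_window_min`, `convergence`, `exponent`.
#' @exportS3Method generics::glance
glance.recovery_fit <- function(x, ...) {
  tibble::tibble(
    rss = x$rss, n_breaths = x$n_breaths,
    alactic_volume_l = alactic_volume(x),
    fit_window_min = x$fit_window_min,
    convergence = x$convergence, exponent = x$exponent
  )
}

#' Tidy an energy partition into long component form
#'
#' @param x An `energy_partition` from [partition_session()].
#' @param ... Unused.
#' @return Tibble with `component`, `volume_l`, `energy_kj`, `fraction`.
#' @exportS3Method generics::tidy
tidy.energy_partition <- function(x, ...) {
  vols <- c(aerobic = x$aerobic_l, alactic = x$alactic_l, lactic = x$lactic_l)
  tibble::tibble(
    component = names(vols),
    volume_l = unname(vols),
    energy_kj = unname(vols) * x$caloric_equiv,
    fraction = unname(vols) / x$total_l
  )
}

#' One-row summary of an energy partition
#'
#' @inheritParams tidy.energy_partition
#' @return Tibble with totals, conversion constant and flags.
#' @exportS3Method generics::glance
glance.energy_partition <- function(x, ...) {
  flags <- attr(x, "flags") %||% list()
  tibble::tibble(
    total_l = x$total_l, total_kj = x$total_kj,
    caloric_equiv = x$caloric_equiv, body_mass = x$body_mass,
    net_lactate_mmol_l = x$net_lactate_mmol_l,
    baseline_vo2_l_min = x$baseline_vo2_l_min,
    negative_aerobic = isTRUE(flags$negative_aerobic),
    lactate_clamped = isTRUE(flags$lactate_clamped)
  )
}

#' Tidy a repeated-measures ANOVA table
#'
#' The [rm_anova()] result is already tidy (one row per effect); this method
#' standardises the column names to broom conventions.
#'
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @return Tibble with `term`, `sumsq`, `df`, `statistic`, `p.value`.
#' @exportS3Method generics::tidy
tidy.rm_anova <- function(x, ...) {
  tibble::tibble(
    term = x$effect, sumsq = x$ss, df = x$df_num,
    statistic = x$F, p.value = x$p
  )
}
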