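#' Plot a breath series
#'
#' Time course of the available channels, coloured by session phase.
#'
#' @param object A [breath_series()].
#' @param channels Channels to show (subset of `vo2`, `vco2`, `ve`, `hr`).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.breath_series <- function(object,
                                   channels = c("vo2", "hr", "ve"), ...) {
  keep <- channels[vapply(channels,
                          function(ch) any(!is.na(object[[ch]])), logical(1))]
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("t", "phase", keep)],
    cols = dplyr::all_of(keep), names_to = "channel", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t / 60, y = .data$value,
                                     colour = .data$phase)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Session time (min)", y = NULL, colour = "Phase") +
    ggplot2::theme_minimal()
}

#' Plot a recovery fit
#'
#' Recovery-phase breaths with the fitted mono-exponential curve and its
#' baseline asymptote.
#'
#' @param object A `recovery_fit` from [fit_off_kinetics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.recovery_fit <- function(object, ...) {
  grid <- tibble::tibble(
    t_min = seq(0, max(object$data$t_min), length.out = 400)
  )
  grid$vo2 <- predict_vo2(object, grid$t_min)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t_min, y = .data$vo2)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.5) +
    ggplot2::geom_line(data = grid, colour = "firebrick", linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = object$baseline, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "Time since exercise end (min)",
                  y = expression(dot(V) * O[2] ~ (L %.% min^-1))) +
    ggplot2::theme_minimal()
}

#' Plot an energy partition
#'
#' Bar chart of the three energy-system oxygen volumes.
#'
#' @param object An `energy_partition` from [partition_session()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.energy_partition <- function(object, ...) {
  long <- tidy.energy_partition(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$component, y = .data$volume_l,
                                     fill = .data$component)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "Oxygen volume (L)") +
    ggplot2::theme_minimal()
}

#' Plot per-condition energy components of a trial
#'
#' Paired per-subject component values under the two conditions, with
#' subject trajectories.
#'
#' @param object A `trial_partitions` tibble from [partition_trial()].
#' @param components Components to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.trial_partitions <- function(object,
                                      components = c("aerobic_l", "alactic_l",
                                                     "lactic_l", "total_l"),
                                      ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("subject_id", "condition", components)],
    cols = dplyr::all_of(components),
    names_to = "component", values_to = "volume_l"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$volume_l)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject_id),
                       alpha = 0.35, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$condition),
                        show.legend = FALSE) +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Oxygen volume (L)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
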