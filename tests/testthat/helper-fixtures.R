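# Fixture builders shared across test files. All data are generated in code.

true_off_kinetics <- function() {
  list(baseline = 0.3, A1 = 0.6, tau1 = 0.75, td = 0.1)
}

# Recovery-only breath series forward-generated from the off-kinetics model;
# time zero is exercise end, so fits use exercise_end_s = 0.
make_recovery_series <- function(params = true_off_kinetics(), spacing = 3,
                                 dur_s = 600, noise = 0, seed = NULL) {
  t <- seq(0, dur_s, by = spacing)
  vo2 <- predict_vo2(params, t / 60)
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    vo2 <- pmax(vo2 + rnorm(length(t), 0, noise), 0)
  }
  breath_series(tibble::tibble(t = t, vo2 = vo2, phase = "recovery"))
}

# Three-phase series with exact phase boundaries and constant or supplied
# per-phase VO2 values, breaths every `spacing` seconds.
make_session_series <- function(rest_s = 300, ex_s = 1800, rec_s = 600,
                                spacing = 3, rest_vo2 = 0.3, ex_vo2 = 1.0,
                                rec_vo2 = 0.4, hr = NA_real_) {
  t <- seq(0, rest_s + ex_s + rec_s - spacing, by = spacing)
  phase <- ifelse(t < rest_s, "rest",
                  ifelse(t < rest_s + ex_s, "exercise", "recovery"))
  vo2 <- ifelse(phase == "rest", rest_vo2,
                ifelse(phase == "exercise", ex_vo2, rec_vo2))
  breath_series(tibble::tibble(t = t, vo2 = vo2, hr = hr, phase = phase))
}

# Canonical lactate profile from explicit pre / post concentrations.
make_lactate_profile <- function(pre, posts = c(2, 2, 2, 2), ex15 = NA,
                                 rec15 = NA) {
  labs <- c("pre", "ex15", "post0", "post3", "post5", "post7", "rec15")
  conc <- c(pre, ex15, posts, rec15)
  keep <- !is.na(conc)
  lactate_profile(tibble::tibble(
    label = labs[keep],
    t_min = c(-5, 15, 30, 33, 35, 37, 45)[keep],
    conc = conc[keep]
  ))
}

# Long-format balanced repeated-measures table from an n x (2k) matrix of
# cell means (subjects in rows, condition-by-time cells in columns).
make_rm_layout <- function(values, times) {
  n <- nrow(values)
  k <- length(times)
  stopifnot(ncol(values) == 2 * k)
  tidyr::expand_grid(subject = sprintf("P%02d", seq_len(n)),
                     condition = c("A", "B"), time = times) |>
    dplyr::arrange(subject, condition, match(time, times)) |>
    dplyr::mutate(value = as.vector(t(values)))
}

# Independent sums-of-squares decomposition of a balanced two-way
# repeated-measures layout, written directly from cell-mean identities.
brute_force_rm_ss <- function(d) {
  grand <- mean(d$value)
  n <- length(unique(d$subject))
  C <- length(unique(d$condition))
  K <- length(unique(d$time))
  m_s <- tapply(d$value, d$subject, mean)
  m_c <- tapply(d$value, d$condition, mean)
  m_t <- tapply(d$value, d$time, mean)
  m_sc <- tapply(d$value, list(d$subject, d$condition), mean)
  m_st <- tapply(d$value, list(d$subject, d$time), mean)
  m_ct <- tapply(d$value, list(d$condition, d$time), mean)

  ss_total <- sum((d$value - grand)^2)
  ss_subject <- C * K * sum((m_s - grand)^2)
  ss_condition <- n * K * sum((m_c - grand)^2)
  ss_time <- n * C * sum((m_t - grand)^2)
  dev_ct <- outer(rownames(m_ct), colnames(m_ct),
                  Vectorize(function(ci, ti) m_ct[ci, ti] - m_c[ci] - m_t[ti] + grand))
  ss_ct <- n * sum(dev_ct^2)
  dev_sc <- outer(rownames(m_sc), colnames(m_sc),
                  Vectorize(function(si, ci) m_sc[si, ci] - m_s[si] - m_c[ci] + grand))
  ss_sc <- K * sum(dev_sc^2)
  dev_st <- outer(rownames(m_st), colnames(m_st),
                  Vectorize(function(si, ti) m_st[si, ti] - m_s[si] - m_t[ti] + grand))
  ss_st <- C * sum(dev_st^2)
  ss_sct <- ss_total - ss_subject - ss_condition - ss_time - ss_ct -
    ss_sc - ss_st

  list(
    total = ss_total, subject = ss_subject,
    condition = ss_condition, time = ss_time, interaction = ss_ct,
    err_condition = ss_sc, err_time = ss_st, err_interaction = ss_sct,
    F_condition = (ss_condition / (C - 1)) / (ss_sc / ((n - 1) * (C - 1))),
    F_time = (ss_time / (K - 1)) / (ss_st / ((n - 1) * (K - 1))),
    F_interaction = (ss_ct / ((C - 1) * (K - 1))) /
      (ss_sct / ((n - 1) * (C - 1) * (K - 1)))
  )
}
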