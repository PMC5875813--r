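#' Paired t-test between crossover conditions
#'
#' Classical two-sided paired t-test on within-subject differences
#' (condition B minus condition A), as used to compare the energy-system
#' totals of the two sessions of a crossover. Degenerate inputs with zero
#' variance of the differences are handled explicitly: identical vectors
#' give `t = 0`, `p = 1`; a constant non-zero difference is flagged
#' `degenerate = TRUE` with `p = 0`.
#'
#' @param data Data frame with one row per subject.
#' @param a,b Column names holding the condition A (e.g. LIE) and condition
#'   B (e.g. LIE-BFR) values.
#' @return One-row tibble: `t`, `df`, `p`, `mean_diff` (B - A), `n`,
#'   `degenerate`.
#' @export
#' @examples
#' d <- tibble::tibble(lie = c(10, 11, 12, 13), bfr = c(11, 13, 15, 17))
#' paired_t(d, a = "lie", b = "bfr")
paired_t <- function(data, a = "value_a", b = "value_b") {
  for (col in c(a, b)) {
    if (!col %in% names(data)) {
      abort(paste0("Column `", col, "` not found."), class = "ergo_format_error")
    }
  }
  va <- as.numeric(data[[a]])
  vb <- as.numeric(data[[b]])
  if (any(is.na(va)) || any(is.na(vb))) {
    abort("Complete pairs are required (no missing values).",
          class = "ergo_validation_error")
  }
  n <- length(va)
  if (n < 2) {
    abort("At least two pairs are required.", class = "ergo_validation_error")
  }
  d <- vb - va
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(tibble::tibble(t = 0, df = n - 1, p = 1, mean_diff = 0,
                            n = n, degenerate = FALSE))
    }
    return(tibble::tibble(t = sign(mean(d)) * Inf, df = n - 1, p = 0,
                          mean_diff = mean(d), n = n, degenerate = TRUE))
  }
  tt <- t.test(vb, va, paired = TRUE)
  tibble::tibble(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, mean_diff = unname(tt$estimate),
    n = n, degenerate = FALSE
  )
}

#' Two-way repeated-measures ANOVA (condition x time)
#'
#' Within-subject sums-of-squares decomposition for a fully crossed,
#' balanced crossover layout (every subject measured in every condition at
#' every time point, one observation per cell), as used to compare lactate,
#' heart-rate and ventilation responses across a session. Each effect
#' (condition, time, condition x time) is tested against its own
#' subject-interaction error stratum. Sphericity is assumed and no
#' correction is applied; this is reported in the `sphericity_assumed`
#' attribute rather than adjusted for.
#'
#' @param data Long-format data frame.
#' @param value,subject,condition,time Column names of the measurement, the
#'   subject identifier, and the two within-subject factors.
#' @return A tibble of class `rm_anova` with one row per effect: `effect`,
#'   `ss`, `ss_error`, `df_num`, `df_den`, `F`, `p`.
#' @export
rm_anova <- function(data, value = "value", subject = "subject",
                     condition = "condition", time = "time") {
  for (col in c(value, subject, condition, time)) {
    if (!col %in% names(data)) {
      abort(paste0("Column `", col, "` not found."), class = "ergo_format_error")
    }
  }
  d <- data.frame(
    value = as.numeric(data[[value]]),
    subject = factor(data[[subject]]),
    condition = factor(data[[condition]]),
    time = factor(data[[time]])
  )
  if (any(is.na(d$value))) {
    abort("Missing cells are not allowed (no imputation).",
          class = "ergo_validation_error")
  }
  counts <- table(d$subject, d$condition, d$time)
  if (any(counts != 1)) {
    abort("Layout must be balanced and complete: exactly one observation per subject x condition x time cell.",
          class = "ergo_validation_error")
  }
  n <- nlevels(d$subject)
  k <- nlevels(d$time)
  if (n < 2 || nlevels(d$condition) < 2 || k < 2) {
    abort("Need >= 2 subjects and >= 2 levels of condition and time.",
          class = "ergo_validation_error")
  }

  fit <- aov(value ~ condition * time + Error(subject / (condition * time)),
             data = d)
  s <- summary(fit)

  pull_row <- function(term) {
    for (stratum in s) {
      tab <- stratum[[1]]
      rn <- trimws(rownames(tab))
      i <- match(term, rn)
      if (!is.na(i)) {
        j <- match("Residuals", rn)
        f <- tab[i, "F value"]
        p <- tab[i, "Pr(>F)"]
        if (tab[i, "Sum Sq"] < 1e-12 && tab[j, "Sum Sq"] < 1e-12) {
          # no effect and no error variation in this stratum: report a null F
          f <- 0
          p <- 1
        }
        return(list(
          ss = tab[i, "Sum Sq"], df_num = tab[i, "Df"],
          ss_error = tab[j, "Sum Sq"], df_den = tab[j, "Df"],
          F = f, p = p
        ))
      }
    }
    abort(paste0("Effect `", term, "` not found in the ANOVA decomposition."),
          class = "ergo_validation_error")
  }

  rows <- list(
    condition = pull_row("condition"),
    time = pull_row("time"),
    interaction = pull_row("condition:time")
  )
  grab <- function(field) unname(vapply(rows, `[[`, numeric(1), field))
  out <- tibble::tibble(
    effect = names(rows),
    ss = grab("ss"),
    ss_error = grab("ss_error"),
    df_num = grab("df_num"),
    df_den = grab("df_den"),
    F = grab("F"),
    p = grab("p")
  )
  attr(out, "n_subjects") <- n
  attr(out, "n_times") <- k
  attr(out, "sphericity_assumed") <- TRUE
  class(out) <- c("rm_anova", class(tibble::tibble()))
  out
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, p * m)` for a family of `m` comparisons, used to localise
#' differences after a significant ANOVA F (here: per-time-point
#' between-condition comparisons, so `m` equals the number of time points).
#'
#' @param p_values Raw p-values in \[0, 1\].
#' @param m Family size (>= number of p-values); defaults to
#'   `length(p_values)`.
#' @return Adjusted p-values.
#' @export
#' @examples
#' bonferroni(0.01, m = 5)  # 0.05
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].", class = "ergo_validation_error")
  }
  if (m < 1) abort("`m` must be >= 1.", class = "ergo_validation_error")
  if (m < length(p_values)) {
    abort("Family size `m` cannot be smaller than the number of p-values.",
          class = "ergo_validation_error")
  }
  p.adjust(p_values, method = "bonferroni", n = m)
}

#' Test-retest typical error and coefficient of variation
#'
#' Typical error `TE = SD(test - retest) / sqrt(2)`; the coefficient of
#' variation expresses it relative to the grand mean of both measurements,
#' `CV = 100 * TE / grand mean`.
#'
#' @param test,retest Equal-length numeric vectors (>= 2 values each).
#' @return One-row tibble: `te`, `cv_percent`, `n`.
#' @export
typical_error_cv <- function(test, retest) {
  if (length(test) != length(retest)) {
    abort("`test` and `retest` must have equal length.",
          class = "ergo_validation_error")
  }
  if (length(test) < 2) {
    abort("At least two paired measurements are required.",
          class = "ergo_validation_error")
  }
  te <- sd(test - retest) / sqrt(2)
  gm <- mean(c(test, retest))
  if (abs(gm) < .Machine$double.eps^0.5) {
    abort("Coefficient of variation undefined: grand mean is zero.",
          class = "ergo_validation_error")
  }
  tibble::tibble(te = te, cv_percent = 100 * te / gm, n = length(test))
}
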