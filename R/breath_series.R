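#' Construct a breath-by-breath gas-exchange series
#'
#' A breath series is a tibble with one row per breath and columns `t`
#' (seconds from session start), `vo2`, `vco2`, `ve` (all L·min^-1, STPD),
#' `hr` (beats·min^-1) and `phase` (one of `rest`, `exercise`, `recovery`).
#' Channels other than `t`, `vo2` and `phase` are optional and may be `NA`;
#' missing breaths of an optional channel are never imputed.
#'
#' Validation enforces: non-negative times and gas volumes, strictly
#' increasing timestamps, heart rate within 20--250 beats·min^-1 where
#' present, and phases forming contiguous blocks in the order
#' rest -> exercise -> recovery (a subset of the three phases is allowed,
#' but never out of order or interleaved).
#'
#' @param breaths Data frame with at least `t`, `vo2` and `phase` columns.
#' @param subject_id Optional subject identifier.
#' @param condition Session condition, `"LIE"` (low-intensity endurance
#'   exercise) or `"LIE_BFR"` (the same exercise with blood-flow restriction),
#'   or `NA` when not applicable.
#' @return A tibble of class `breath_series` with attributes `subject_id`
#'   and `condition`.
#' @export
#' @examples
#' b <- tibble::tibble(
#'   t = c(0, 3, 6), vo2 = c(0.3, 0.31, 0.29),
#'   phase = c("rest", "rest", "rest")
#' )
#' breath_series(b)
breath_series <- function(breaths, subject_id = NA_character_,
                          condition = NA_character_) {
  if (!is.data.frame(breaths)) {
    abort("`breaths` must be a data frame.", class = "ergo_format_error")
  }
  required <- c("t", "vo2", "phase")
  missing_cols <- setdiff(required, names(breaths))
  if (length(missing_cols) > 0) {
    abort(
      paste0("Missing required column(s): ", paste(missing_cols, collapse = ", ")),
      class = "ergo_format_error"
    )
  }
  x <- tibble::as_tibble(breaths)
  for (ch in c("vco2", "ve", "hr")) {
    if (!ch %in% names(x)) x[[ch]] <- NA_real_
  }
  x <- x[, c("t", "vo2", "vco2", "ve", "hr", "phase")]
  x$t <- as.numeric(x$t)
  for (ch in c("vo2", "vco2", "ve", "hr")) x[[ch]] <- as.numeric(x[[ch]])
  x$phase <- as.character(x$phase)

  validate_breaths(x)

  structure(
    x,
    subject_id = subject_id,
    condition = if (is.na(condition)) NA_character_ else match.arg(condition, c("LIE", "LIE_BFR")),
    class = c("breath_series", class(tibble::tibble()))
  )
}

phase_levels <- function() c("rest", "exercise", "recovery")

validate_breaths <- function(x) {
  if (nrow(x) == 0) {
    abort("Breath series is empty.", class = "ergo_validation_error")
  }
  if (any(x$t < 0)) {
    abort("Breath times must be non-negative.", class = "ergo_validation_error")
  }
  bad_t <- which(diff(x$t) <= 0)
  if (length(bad_t) > 0) {
    abort(
      paste0("Breath times must be strictly increasing; first violation at row ",
             bad_t[1] + 1, " (t = ", x$t[bad_t[1] + 1], ")."),
      class = "ergo_validation_error"
    )
  }
  for (ch in c("vo2", "vco2", "ve")) {
    v <- x[[ch]]
    if (any(!is.na(v) & v < 0)) {
      abort(paste0("Channel `", ch, "` must be non-negative."),
            class = "ergo_validation_error")
    }
  }
  hr <- x$hr[!is.na(x$hr)]
  if (length(hr) > 0 && (any(hr < 20) || any(hr > 250))) {
    abort("Heart rate out of the plausible range [20, 250] beats/min.",
          class = "ergo_validation_error")
  }
  unknown <- setdiff(unique(x$phase), phase_levels())
  if (length(unknown) > 0) {
    abort(paste0("Unknown phase label(s): ", paste(unknown, collapse = ", "),
                 ". Expected rest, exercise, recovery."),
          class = "ergo_validation_error")
  }
  blocks <- rle(x$phase)$values
  if (anyDuplicated(blocks) > 0) {
    abort("Each phase must form a single contiguous block.",
          class = "ergo_validation_error")
  }
  if (is.unsorted(match(blocks, phase_levels()))) {
    abort("Phases must appear in the order rest -> exercise -> recovery.",
          class = "ergo_validation_error")
  }
  invisible(x)
}

#' Phase boundaries of a breath series
#'
#' Returns one row per phase present, with the phase start (time of its first
#' breath), its end (the start of the next phase, or for the last phase the
#' last breath time plus the median breath interval), and the span in seconds.
#'
#' @param series A [breath_series()].
#' @return Tibble with columns `phase`, `start`, `end`, `span_s`, `n_breaths`.
#' @export
phase_bounds <- function(series) {
  stopifnot(inherits(series, "breath_series"))
  dt <- median(diff(series$t))
  if (!is.finite(dt)) dt <- 0
  ph <- rle(series$phase)$values
  starts <- vapply(ph, function(p) series$t[series$phase == p][1], numeric(1))
  ends <- c(starts[-1], max(series$t) + dt)
  tibble::tibble(
    phase = ph,
    start = unname(starts),
    end = unname(ends),
    span_s = unname(ends - starts),
    n_breaths = vapply(ph, function(p) sum(series$phase == p), integer(1))
  )
}

#' Read a breath-by-breath CSV file
#'
#' Expects a comma-separated file with a header row. The default dialect has
#' columns `time_s, vo2_l_min, vco2_l_min, ve_l_min, hr_bpm, phase`; other
#' layouts are handled through `column_map`. Oxygen uptake may be supplied in
#' L·min^-1, mL·min^-1 or mL·kg^-1·min^-1 (the latter requires `body_mass`);
#' values are normalised to L·min^-1 on ingest.
#'
#' @param path Path to the CSV file.
#' @param column_map Named list mapping internal names (`t`, `vo2`, `vco2`,
#'   `ve`, `hr`, `phase`) to file column names. `t`, `vo2` and `phase` are
#'   required; map an optional channel to `NULL` to drop it.
#' @param vo2_unit Unit of the V-dot-O2 (and V-dot-CO2) columns in the file:
#'   `"l_min"`, `"ml_min"` or `"ml_kg_min"`.
#' @param body_mass Body mass in kg; required when `vo2_unit = "ml_kg_min"`.
#' @inheritParams breath_series
#' @return A [breath_series()].
#' @export
read_breath_csv <- function(path,
                            column_map = breath_column_map(),
                            vo2_unit = c("l_min", "ml_min", "ml_kg_min"),
                            body_mass = NULL,
                            subject_id = NA_character_,
                            condition = NA_character_) {
  vo2_unit <- match.arg(vo2_unit)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "ergo_format_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cm <- utils::modifyList(breath_column_map(), column_map)
  for (key in c("t", "vo2", "phase")) {
    col <- cm[[key]]
    if (is.null(col) || !col %in% names(raw)) {
      abort(
        paste0("Required column `", key, "` (mapped to '",
               if (is.null(col)) "<unmapped>" else col,
               "') not found in ", path),
        class = "ergo_format_error"
      )
    }
  }
  out <- tibble::tibble(
    t = as.numeric(raw[[cm$t]]),
    vo2 = as.numeric(raw[[cm$vo2]]),
    phase = as.character(raw[[cm$phase]])
  )
  for (ch in c("vco2", "ve", "hr")) {
    col <- cm[[ch]]
    out[[ch]] <- if (!is.null(col) && col %in% names(raw)) as.numeric(raw[[col]]) else NA_real_
  }
  scale <- switch(vo2_unit,
    l_min = 1,
    ml_min = 1e-3,
    ml_kg_min = {
      if (is.null(body_mass) || body_mass <= 0) {
        abort("`body_mass` (kg) is required when vo2_unit = 'ml_kg_min'.",
              class = "ergo_format_error")
      }
      body_mass * 1e-3
    }
  )
  out$vo2 <- out$vo2 * scale
  out$vco2 <- out$vco2 * scale
  breath_series(out, subject_id = subject_id, condition = condition)
}

#' Default breath CSV column mapping
#' @return Named list usable as `column_map` in [read_breath_csv()].
#' @export
breath_column_map <- function() {
  list(t = "time_s", vo2 = "vo2_l_min", vco2 = "vco2_l_min",
       ve = "ve_l_min", hr = "hr_bpm", phase = "phase")
}

#' Write a breath series to CSV
#'
#' Writes the default dialect (`time_s, vo2_l_min, vco2_l_min, ve_l_min,
#' hr_bpm, phase`), so that [read_breath_csv()] round-trips all numeric
#' fields.
#'
#' @param series A [breath_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_breath_csv <- function(series, path) {
  stopifnot(inherits(series, "breath_series"))
  out <- tibble::tibble(
    time_s = series$t,
    vo2_l_min = series$vo2,
    vco2_l_min = series$vco2,
    ve_l_min = series$ve,
    hr_bpm = series$hr,
    phase = series$phase
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Per-phase windowed channel averages
#'
#' Averages a channel in consecutive half-open windows `[start, start + w)`
#' anchored at the start of each phase, keeping only complete windows (the
#' field convention of reporting heart rate and ventilation as 5-min means of
#' rest, exercise and recovery). The mean of a window is the arithmetic mean
#' of the breaths whose timestamp falls inside it.
#'
#' @param series A [breath_series()].
#' @param channel One of `"hr"`, `"ve"`, `"vo2"`.
#' @param window Window length in seconds (default 300 s = 5 min).
#' @return Tibble with columns `phase`, `window_index`, `window_start`,
#'   `window_end`, `channel`, `mean_value`, `n_breaths`.
#' @export
bin_phase_averages <- function(series, channel = c("hr", "ve", "vo2"),
                               window = 300) {
  stopifnot(inherits(series, "breath_series"))
  channel <- match.arg(channel)
  if (!is.numeric(window) || window <= 0) {
    abort("`window` must be a positive number of seconds.",
          class = "ergo_validation_error")
  }
  pb <- phase_bounds(series)
  res <- list()
  for (i in seq_len(nrow(pb))) {
    n_win <- floor(pb$span_s[i] / window)
    if (n_win < 1) next
    for (w in seq_len(n_win)) {
      ws <- pb$start[i] + (w - 1) * window
      we <- ws + window
      sel <- series$phase == pb$phase[i] & series$t >= ws & series$t < we
      vals <- series[[channel]][sel]
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0) {
        abort(
          paste0("Empty averaging window [", ws, ", ", we, ") s in phase '",
                 pb$phase[i], "' for channel '", channel, "'."),
          class = "ergo_validation_error"
        )
      }
      res[[length(res) + 1]] <- tibble::tibble(
        phase = pb$phase[i], window_index = w,
        window_start = ws, window_end = we,
        channel = channel, mean_value = mean(vals),
        n_breaths = length(vals)
      )
    }
  }
  if (length(res) == 0) {
    abort(
      paste0("No phase contains a complete ", window,
             " s window; series too short for this window."),
      class = "ergo_validation_error"
    )
  }
  dplyr::bind_rows(res)
}

#' Resting baseline oxygen uptake
#'
#' Mean V-dot-O2 over the final `window` seconds of the rest phase (default
#' 120 s), discarding the un-steady early minutes of seated rest. The mean is
#' the arithmetic mean of the breaths covered by the half-open window
#' `[rest_end - window, rest_end)`.
#'
#' @param series A [breath_series()] containing a rest phase.
#' @param window Averaging window in seconds, default 120.
#' @return Baseline V-dot-O2 in L·min^-1.
#' @export
baseline_vo2 <- function(series, window = 120) {
  stopifnot(inherits(series, "breath_series"))
  pb <- phase_bounds(series)
  if (!"rest" %in% pb$phase) {
    abort("Series has no rest phase.", class = "ergo_validation_error")
  }
  row <- pb[pb$phase == "rest", ]
  if (row$span_s < window) {
    abort(
      paste0("Rest phase spans ", round(row$span_s, 1),
             " s, shorter than the baseline window (", window, " s)."),
      class = "ergo_validation_error"
    )
  }
  sel <- series$phase == "rest" & series$t >= row$end - window & series$t < row$end
  vals <- series$vo2[sel]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    abort("No breaths inside the baseline window.", class = "ergo_validation_error")
  }
  mean(vals)
}

#' @export
print.breath_series <- function(x, ...) {
  sid <- attr(x, "subject_id")
  cond <- attr(x, "condition")
  cat("<breath_series> ", nrow(x), " breaths",
      if (!is.na(sid)) paste0(" | subject ", sid) else "",
      if (!is.na(cond)) paste0(" | ", cond) else "", "\n", sep = "")
  pb <- phase_bounds(x)
  for (i in seq_len(nrow(pb))) {
    cat(sprintf("  %-9s %7.1f - %7.1f s  (%d breaths)\n",
                pb$phase[i], pb$start[i], pb$end[i], pb$n_breaths[i]))
  }
  NextMethod()
}
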