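#' Fill short gaps in a 1-Hz heart-rate record
#'
#' Chest-strap telemetry occasionally drops samples. Gaps of up to
#' `max_gap` consecutive missing values are filled by linear interpolation
#' between the neighbouring valid samples; longer gaps, or missing values at
#' either end of the record, are an error because interpolation there would
#' fabricate dynamics.
#'
#' @param data Tibble with `time_s` and `hr_bpm` columns.
#' @param max_gap Longest run of consecutive missing samples that may be
#'   interpolated (default 3).
#' @return `data` with `hr_bpm` gap-filled.
#' @export
fill_missing_hr <- function(data, max_gap = 3L) {
  hr <- data$hr_bpm
  if (!anyNA(hr)) return(data)
  na <- is.na(hr)
  if (na[1] || na[length(na)]) {
    abort("Missing heart-rate samples at the record boundary cannot be interpolated.")
  }
  runs <- rle(na)
  if (max(runs$lengths[runs$values]) > max_gap) {
    abort(sprintf(
      "A gap of %d consecutive missing heart-rate samples exceeds the %d-sample interpolation limit.",
      max(runs$lengths[runs$values]), max_gap
    ))
  }
  filled <- stats::approx(data$time_s[!na], hr[!na], xout = data$time_s,
                          method = "linear")$y
  inform(sprintf("Interpolated %d missing heart-rate sample(s).", sum(na)))
  data$hr_bpm <- filled
  data
}

#' Downsample a record by block averaging
#'
#' Reduces a 1-Hz record to a 0.2-Hz record by averaging consecutive,
#' non-overlapping batches of `batch` samples (default 5, i.e. a 5-s output
#' period). Every numeric signal column is block-averaged; the output sample
#' time is the first time of each batch, so a record starting at 0 s yields
#' samples at 0, 5, 10, ... s. A trailing remainder shorter than a full
#' batch is dropped with a message.
#'
#' @param data Tibble with a `time_s` column on a uniform grid plus one or
#'   more numeric signal columns (e.g. `speed_mps`, `hr_bpm`).
#' @param batch Samples per batch (default 5).
#' @return A tibble on the coarser grid with the same columns.
#' @export
#' @examples
#' downsample_hr(tibble::tibble(time_s = 0:4, hr_bpm = 1:5))  # mean 3
downsample_hr <- function(data, batch = 5L) {
  batch <- as.integer(batch)
  n <- nrow(data)
  if (is.null(n) || n == 0L) abort("`data` is empty.")
  if (batch < 1L) abort("`batch` must be at least 1.")
  infer_sample_period(data$time_s)
  n_out <- n %/% batch
  if (n_out == 0L) abort("`data` is shorter than one batch.")
  if (n %% batch != 0L) {
    inform(sprintf("Dropping %d trailing sample(s) not filling a batch.", n %% batch))
  }
  keep <- seq_len(n_out * batch)
  grp <- rep(seq_len(n_out), each = batch)
  out <- data[seq(1, n_out * batch, by = batch), , drop = FALSE]
  sig_cols <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], "time_s")
  for (cl in sig_cols) {
    out[[cl]] <- as.numeric(tapply(data[[cl]][keep], grp, mean))
  }
  tibble::as_tibble(out)
}

#' Extract an evaluation window from a record
#'
#' Returns the inclusive slice of `data` whose sample times fall on the
#' window's grid, checking that the record's grid is aligned with the
#' window (same period, matching phase) and that the slice contains exactly
#' `window$n_samples` points.
#'
#' @param data Tibble with a uniform `time_s` column.
#' @param window An [eval_window()].
#' @return The windowed tibble with `window$n_samples` rows.
#' @export
extract_window <- function(data, window) {
  stopifnot(inherits(window, "eval_window"))
  dt <- infer_sample_period(data$time_s)
  if (abs(dt - window$sample_period_s) > 1e-9 * window$sample_period_s) {
    abort(sprintf("Record period (%g s) does not match the window period (%g s).",
                  dt, window$sample_period_s))
  }
  phase <- (window$start_time_s - data$time_s[1]) / dt
  if (abs(phase - round(phase)) > 1e-6) {
    abort("Window start does not fall on the record's sample grid.")
  }
  keep <- data$time_s >= window$start_time_s - 1e-9 &
    data$time_s <= window$end_time_s + 1e-9
  out <- data[keep, , drop = FALSE]
  if (nrow(out) != window$n_samples) {
    abort(sprintf("Window requires %d samples but the record provides %d.",
                  window$n_samples, nrow(out)))
  }
  tibble::as_tibble(out)
}

#' Remove mean and linear trend from the heart-rate output
#'
#' Subtracts the least-squares straight line (intercept plus slope in time)
#' from the heart-rate signal over its window, yielding the output deviation
#' `y_bpm`. This removes the operating-point level and any slow Phase III
#' drift, leaving the small-signal response the linear models describe. The
#' operation is idempotent: detrending a detrended signal changes nothing.
#'
#' @param data Tibble with `time_s` and the column named by `value`.
#' @param value Name of the heart-rate column (default `"hr_bpm"`).
#' @return `data` with an added `y_bpm` column; the removed intercept and
#'   slope (at the window's own time origin) are attached as the
#'   `trend_coefficients` attribute.
#' @export
detrend_output <- function(data, value = "hr_bpm") {
  if (nrow(data) < 3L) abort("Detrending requires at least 3 samples.")
  y <- data[[value]]
  if (anyNA(y)) abort("Detrending requires complete data; fill gaps first.")
  tt <- data$time_s - data$time_s[1]
  fit <- lm(y ~ tt)
  data$y_bpm <- as.numeric(stats::residuals(fit))
  attr(data, "trend_coefficients") <- c(
    intercept_bpm = unname(coef(fit)[1]),
    slope_bpm_per_s = unname(coef(fit)[2])
  )
  data
}

#' Remove the mean from the speed input
#'
#' Subtracts the window mean from the speed signal, yielding the input
#' deviation `u_mps`. Over a balanced window (equal counts at the two PRBS
#' levels) the deviation takes exactly the values plus/minus the PRBS
#' half-amplitude.
#'
#' @param data Tibble with the column named by `value`.
#' @param value Name of the speed column (default `"speed_mps"`).
#' @return `data` with an added `u_mps` column; the removed mean is attached
#'   as the `input_mean` attribute.
#' @export
remove_mean_input <- function(data, value = "speed_mps") {
  if (nrow(data) == 0L) abort("`data` is empty.")
  v <- data[[value]]
  data$u_mps <- v - mean(v)
  attr(data, "input_mean") <- mean(v)
  data
}

#' Preprocess a raw test record into an evaluation segment
#'
#' Applies the full preprocessing chain to one 1-Hz test record: fill short
#' heart-rate gaps, downsample to a 5-s period by block averaging, slice the
#' evaluation window (selected for balance from the record's own speed
#' signal unless supplied), remove mean and linear trend from the heart
#' rate, and remove the mean from the speed. The result is the detrended
#' input/output deviation pair on which models are estimated and validated.
#'
#' @param record Tibble with `time_s`, `speed_mps`, `hr_bpm` at 1 Hz (or the
#'   target grid already, in which case downsampling is skipped).
#' @param window Optional [eval_window()]; selected with
#'   [select_balanced_window()] from the downsampled speed when `NULL`.
#' @param n_samples,offset_s Window-selection parameters when `window` is
#'   `NULL` (defaults 360 samples from 290 s on).
#' @param target_period_s Output sample period in seconds (default 5); the
#'   downsampling batch size is the ratio of this to the record's period.
#' @return A tibble with columns `time_s`, `u_mps`, `y_bpm`, carrying
#'   `window`, `trend_coefficients` and `input_mean` attributes.
#' @export
preprocess_record <- function(record, window = NULL, n_samples = 360L,
                              offset_s = 290, target_period_s = 5) {
  record <- fill_missing_hr(record)
  dt <- infer_sample_period(record$time_s)
  ratio <- target_period_s / dt
  if (ratio < 1 - 1e-9) {
    abort("`record` is coarser than the target sample period.")
  }
  if (abs(ratio - round(ratio)) > 1e-6) {
    abort("Target sample period must be an integer multiple of the record's period.")
  }
  batch <- as.integer(round(ratio))
  ds <- if (batch > 1L) downsample_hr(record, batch = batch) else record
  if (is.null(window)) {
    window <- select_balanced_window(ds, n_samples = n_samples,
                                     offset_s = offset_s)
  }
  seg <- extract_window(ds, window)
  seg <- detrend_output(seg)
  seg <- remove_mean_input(seg)
  out <- tibble::tibble(
    time_s = seg$time_s,
    u_mps = seg$u_mps,
    y_bpm = seg$y_bpm
  )
  attr(out, "window") <- window
  attr(out, "trend_coefficients") <- attr(seg, "trend_coefficients")
  attr(out, "input_mean") <- attr(seg, "input_mean")
  out
}
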