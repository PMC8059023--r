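#' PRBS excitation specification
#'
#' Describes the pseudo-random binary sequence (PRBS) used to excite the
#' treadmill speed around its operating point. The sequence is produced by a
#' maximal-length linear-feedback shift register (LFSR): for a register of
#' order \eqn{m} with a maximal feedback-tap set, the bit sequence repeats
#' with period \eqn{2^m - 1}. Each bit is held for `clock_period_s` seconds;
#' bit 1 maps to `mean_speed + half_amplitude` and bit 0 to
#' `mean_speed - half_amplitude` (m/s).
#'
#' The default is the fifth-order register with feedback taps at stages 5 and
#' 3 (the standard maximal-length polynomial \eqn{x^5 + x^3 + 1}) seeded with
#' the all-ones state, a clock period of 60 s, and an amplitude of
#' \eqn{\pm 0.25} m/s. With these defaults the 31-bit period lasts 1860 s and
#' a 360-sample evaluation window at a 5-s sample period spans 30 of the 31
#' bit-periods, which is what makes an exactly balanced (180 low / 180 high)
#' window possible.
#'
#' @param mean_speed Mid-level treadmill speed \eqn{v_m} in m/s.
#' @param half_amplitude Half peak-to-peak excitation amplitude in m/s
#'   (default 0.25, i.e. speed switches between \eqn{v_m \pm 0.25}).
#' @param register_order LFSR register length (default 5).
#' @param feedback_taps Integer vector of register stages fed back through
#'   XOR; must yield a maximal-length sequence.
#' @param initial_state Bit vector (0/1) of length `register_order`; must not
#'   be all zero. Default all ones.
#' @param clock_period_s Seconds each PRBS bit is held (default 60).
#'
#' @return An object of class `prbs_spec`.
#' @seealso [prbs_bits()], [speed_profile()], [select_balanced_window()]
#' @export
#' @examples
#' spec <- prbs_spec(mean_speed = 2)
#' prbs_bits(spec, 31)
prbs_spec <- function(mean_speed,
                      half_amplitude = 0.25,
                      register_order = 5L,
                      feedback_taps = c(5L, 3L),
                      initial_state = rep(1L, register_order),
                      clock_period_s = 60) {
  if (!is.numeric(mean_speed) || length(mean_speed) != 1L || !is.finite(mean_speed)) {
    abort("`mean_speed` must be a single finite number (m/s).")
  }
  if (!is.numeric(half_amplitude) || length(half_amplitude) != 1L || half_amplitude <= 0) {
    abort("`half_amplitude` must be a single positive number (m/s).")
  }
  register_order <- as.integer(register_order)
  if (register_order < 2L) abort("`register_order` must be at least 2.")
  feedback_taps <- sort(unique(as.integer(feedback_taps)))
  if (any(feedback_taps < 1L) || any(feedback_taps > register_order)) {
    abort("`feedback_taps` must lie between 1 and `register_order`.")
  }
  initial_state <- as.integer(initial_state)
  if (length(initial_state) != register_order || !all(initial_state %in% c(0L, 1L))) {
    abort("`initial_state` must be a 0/1 vector of length `register_order`.")
  }
  if (all(initial_state == 0L)) {
    abort("`initial_state` must not be all zero (the LFSR would be stuck).")
  }
  if (!is.numeric(clock_period_s) || clock_period_s <= 0) {
    abort("`clock_period_s` must be positive.")
  }
  structure(
    list(
      mean_speed = mean_speed,
      half_amplitude = half_amplitude,
      register_order = register_order,
      feedback_taps = feedback_taps,
      initial_state = initial_state,
      clock_period_s = clock_period_s
    ),
    class = "prbs_spec"
  )
}

#' @export
print.prbs_spec <- function(x, ...) {
  cat("<prbs_spec>\n")
  cat("  register order :", x$register_order,
      " (period", 2^x$register_order - 1, "bits)\n")
  cat("  feedback taps  :", paste(x$feedback_taps, collapse = ", "), "\n")
  cat("  initial state  :", paste(x$initial_state, collapse = ""), "\n")
  cat("  clock period   :", x$clock_period_s, "s per bit\n")
  cat("  speed levels   :", x$mean_speed - x$half_amplitude, "/",
      x$mean_speed + x$half_amplitude, "m/s\n")
  invisible(x)
}

# raw Fibonacci LFSR stepper; returns list(bits, states visited)
lfsr_run <- function(state, taps, order, n) {
  bits <- integer(n)
  for (i in seq_len(n)) {
    bits[i] <- state[order]
    fb <- Reduce(bitwXor, state[taps])
    state <- c(fb, state[-order])
  }
  bits
}

# period of the LFSR state cycle starting from `state` (brute-force detection)
lfsr_period <- function(state, taps, order) {
  start <- state
  limit <- 2^order
  for (i in seq_len(limit)) {
    fb <- Reduce(bitwXor, state[taps])
    state <- c(fb, state[-order])
    if (identical(state, start)) return(i)
  }
  NA_integer_
}

#' Generate PRBS bits
#'
#' Runs the linear-feedback shift register described by `spec` and returns the
#' first `n_bits` output bits. The tap set is verified to be maximal-length
#' (state cycle of exactly \eqn{2^{order} - 1}); non-maximal tap sets are
#' rejected because their shorter period destroys the flat excitation
#' spectrum the identification relies on.
#'
#' @param spec A [prbs_spec()].
#' @param n_bits Number of bits to generate (>= 1). The sequence repeats with
#'   period \eqn{2^{order} - 1}.
#' @return Integer vector of 0/1 bits of length `n_bits`.
#' @export
#' @examples
#' bits <- prbs_bits(prbs_spec(2), 31)
#' sum(bits)  # 16 ones, 15 zeros in one period
prbs_bits <- function(spec, n_bits) {
  stopifnot(inherits(spec, "prbs_spec"))
  n_bits <- as.integer(n_bits)
  if (is.na(n_bits) || n_bits < 1L) abort("`n_bits` must be at least 1.")
  full <- 2^spec$register_order - 1
  per <- lfsr_period(spec$initial_state, spec$feedback_taps, spec$register_order)
  if (is.na(per) || per != full) {
    abort(sprintf(
      "Feedback taps {%s} are not maximal-length for order %d: state period %s < %d.",
      paste(spec$feedback_taps, collapse = ", "), spec$register_order,
      ifelse(is.na(per), "undetected", as.character(per)), full
    ))
  }
  lfsr_run(spec$initial_state, spec$feedback_taps, spec$register_order, n_bits)
}

#' Build a treadmill speed profile from PRBS bits
#'
#' Expands a bit sequence into a uniformly sampled two-level speed signal:
#' each bit is held for `clock_period_s / sample_period_s` consecutive
#' samples, with bit 1 mapped to `mean_speed + half_amplitude` and bit 0 to
#' `mean_speed - half_amplitude`.
#'
#' @param bits Integer 0/1 vector, e.g. from [prbs_bits()].
#' @param spec The [prbs_spec()] providing speed levels and clock period.
#' @param sample_period_s Output sample period in seconds; must divide the
#'   clock period exactly.
#' @param duration_s Total profile duration in seconds; must not exceed
#'   `length(bits) * clock_period_s`. The profile contains samples at times
#'   `0, sample_period_s, ...` strictly below `duration_s`.
#' @return A tibble with columns `time_s` and `speed_mps`, carrying the
#'   `mean_speed` and `half_amplitude` as attributes.
#' @export
#' @examples
#' spec <- prbs_spec(mean_speed = 2)
#' prof <- speed_profile(prbs_bits(spec, 36), spec,
#'                       sample_period_s = 5, duration_s = 2160)
#' unique(prof$speed_mps)  # 1.75 and 2.25 m/s
speed_profile <- function(bits, spec, sample_period_s, duration_s) {
  stopifnot(inherits(spec, "prbs_spec"))
  bits <- as.integer(bits)
  if (!all(bits %in% c(0L, 1L))) abort("`bits` must contain only 0 and 1.")
  ratio <- spec$clock_period_s / sample_period_s
  if (abs(ratio - round(ratio)) > 1e-9) {
    abort(sprintf(
      "Clock period (%g s) must be an integer multiple of the sample period (%g s).",
      spec$clock_period_s, sample_period_s
    ))
  }
  ratio <- as.integer(round(ratio))
  if (duration_s > length(bits) * spec$clock_period_s + 1e-9) {
    abort("`duration_s` exceeds the span of the supplied bits.")
  }
  n <- as.integer(floor(duration_s / sample_period_s + 1e-9))
  lev <- rep(bits, each = ratio)[seq_len(n)]
  out <- tibble::tibble(
    time_s = (seq_len(n) - 1) * sample_period_s,
    speed_mps = spec$mean_speed + ifelse(lev == 1L, spec$half_amplitude,
                                         -spec$half_amplitude)
  )
  attr(out, "mean_speed") <- spec$mean_speed
  attr(out, "half_amplitude") <- spec$half_amplitude
  out
}

#' Evaluation window
#'
#' A contiguous, uniformly sampled segment over which models are estimated
#' and validated. Constructed directly or, more usually, with
#' [select_balanced_window()], which enforces the balance requirement that
#' the window contain equally many high-speed and low-speed input samples.
#'
#' @param start_time_s,end_time_s Window limits in seconds (inclusive).
#' @param sample_period_s Sample period in seconds.
#' @return An `eval_window` object with fields `start_time_s`, `end_time_s`,
#'   `sample_period_s` and `n_samples`.
#' @export
eval_window <- function(start_time_s, end_time_s, sample_period_s) {
  n <- (end_time_s - start_time_s) / sample_period_s + 1
  if (abs(n - round(n)) > 1e-9 || n < 1) {
    abort("Window limits must span an integer number of sample periods.")
  }
  structure(
    list(
      start_time_s = start_time_s,
      end_time_s = end_time_s,
      sample_period_s = sample_period_s,
      n_samples = as.integer(round(n))
    ),
    class = "eval_window"
  )
}

#' @export
print.eval_window <- function(x, ...) {
  cat(sprintf("<eval_window> %g s to %g s, %d samples at %g s\n",
              x$start_time_s, x$end_time_s, x$n_samples, x$sample_period_s))
  invisible(x)
}

#' Select a balanced evaluation window
#'
#' Finds the earliest contiguous window of `n_samples` samples, starting at
#' or after `offset_s`, in which the two speed levels occur equally often
#' (e.g. 180 low and 180 high samples for the default 360-sample window).
#' Balance makes the mean-removed input deviation exactly
#' \eqn{\pm} half-amplitude and avoids biasing the estimated steady-state
#' gain. The offset excludes the initial on-transient of the heart-rate
#' response; the search is deterministic so a given profile always yields the
#' same window.
#'
#' @param profile Speed profile tibble (`time_s`, `speed_mps`) with exactly
#'   two distinct speed values, e.g. from [speed_profile()].
#' @param n_samples Window length in samples; must be even (default 360).
#' @param offset_s Transient-exclusion offset in seconds: the window starts
#'   at the first sample time >= `offset_s` for which balance holds
#'   (default 290).
#' @return An [eval_window()].
#' @export
#' @examples
#' spec <- prbs_spec(mean_speed = 2)
#' prof <- speed_profile(prbs_bits(spec, 36), spec, 5, 2160)
#' select_balanced_window(prof)  # 290 s to 2085 s, 360 samples
select_balanced_window <- function(profile, n_samples = 360L, offset_s = 290) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 2L || n_samples %% 2L != 0L) {
    abort("`n_samples` must be a positive even integer.")
  }
  tt <- profile$time_s
  vv <- profile$speed_mps
  dt <- infer_sample_period(tt)
  levels <- sort(unique(vv))
  if (length(levels) != 2L) {
    abort("`profile` must take exactly two speed levels to define balance.")
  }
  is_high <- vv == levels[2]
  first <- which(tt >= offset_s - 1e-9)[1]
  if (is.na(first)) abort("`offset_s` lies beyond the end of the profile.")
  last_start <- length(vv) - n_samples + 1L
  if (last_start < first) {
    abort("Profile too short to contain a window of `n_samples` after the offset.")
  }
  target <- n_samples %/% 2L
  best_gap <- Inf
  # rolling count of high samples over candidate windows
  n_high <- sum(is_high[first:(first + n_samples - 1L)])
  for (s in first:last_start) {
    if (s > first) {
      n_high <- n_high - is_high[s - 1L] + is_high[s + n_samples - 1L]
    }
    if (n_high == target) {
      return(eval_window(tt[s], tt[s + n_samples - 1L], dt))
    }
    best_gap <- min(best_gap, abs(n_high - target))
  }
  abort(sprintf(
    "No balanced %d-sample window found at or after %g s (closest imbalance: %d samples).",
    n_samples, offset_s, as.integer(best_gap)
  ))
}

# sample period of a strictly increasing uniform grid
infer_sample_period <- function(time_s) {
  if (length(time_s) < 2L) abort("Need at least two samples to infer the grid.")
  d <- diff(time_s)
  if (any(d <= 0) || max(d) - min(d) > 1e-6 * mean(d)) {
    abort("Sample times must be strictly increasing and uniformly spaced.")
  }
  mean(d)
}
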