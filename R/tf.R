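#' Continuous-time transfer-function model of heart-rate dynamics
#'
#' Represents the small-signal response from treadmill-speed deviation
#' (m/s) to heart-rate deviation (bpm) as a strictly proper, stable,
#' unit-numerator transfer function:
#' first order \deqn{P_1(s) = k_1 / (\tau_1 s + 1)} which lumps the Phase I
#' and Phase II components into a single mean response time, or second order
#' \deqn{P_2(s) = k_2 / ((\tau_{21} s + 1)(\tau_{22} s + 1))} with separate
#' Phase I and Phase II time constants. The gain \eqn{k} is the steady-state
#' (DC) heart-rate change per unit speed change, in bpm per m/s.
#'
#' Time constants are stored sorted ascending; the response is symmetric in
#' them, so the order carries no information.
#'
#' @param gain Steady-state gain in bpm per m/s (finite; any sign).
#' @param time_constants Numeric vector of 1 (first-order) or 2
#'   (second-order) positive time constants in seconds.
#' @return An object of class `hr_tf`.
#' @export
#' @examples
#' tf_model(28.57, 70.56)          # first-order
#' tf_model(24.70, c(18.60, 37.95)) # second-order
tf_model <- function(gain, time_constants) {
  if (!is.numeric(gain) || length(gain) != 1L || !is.finite(gain)) {
    abort("`gain` must be a single finite number (bpm per m/s).")
  }
  time_constants <- as.numeric(time_constants)
  if (!length(time_constants) %in% c(1L, 2L)) {
    abort("`time_constants` must have length 1 (first order) or 2 (second order).")
  }
  if (any(!is.finite(time_constants)) || any(time_constants <= 0)) {
    abort("All time constants must be positive and finite.")
  }
  structure(
    list(
      order = length(time_constants),
      gain = gain,
      time_constants = sort(time_constants)
    ),
    class = "hr_tf"
  )
}

#' @export
print.hr_tf <- function(x, digits = 4, ...) {
  k <- format(x$gain, digits = digits)
  tc <- format(x$time_constants, digits = digits)
  if (x$order == 1L) {
    cat(sprintf("<hr_tf> P(s) = %s / (%s s + 1)\n", k, tc[1]))
  } else {
    cat(sprintf("<hr_tf> P(s) = %s / ((%s s + 1)(%s s + 1))\n", k, tc[1], tc[2]))
  }
  invisible(x)
}

#' @export
tidy.hr_tf <- function(x, ...) {
  tibble::tibble(
    term = c("gain", paste0("tau", seq_len(x$order))),
    estimate = c(x$gain, x$time_constants)
  )
}

#' Simulate the sampled response of a transfer-function model
#'
#' Computes the zero-initial-state response of an [tf_model()] to a
#' piecewise-constant (zero-order-hold) input sampled on a uniform grid.
#' The discretisation is exact for ZOH inputs — the continuous-time state
#' matrix is exponentiated in closed form per mode — not an Euler
#' approximation, so the sampled output coincides with the continuous-time
#' solution at the sample instants up to floating-point error.
#'
#' @param model An [tf_model()].
#' @param u Numeric vector: the input deviation signal (m/s), assumed held
#'   constant over each sample interval.
#' @param sample_period_s Sample period in seconds (> 0).
#' @return Numeric vector of the same length as `u`: the output deviation in
#'   bpm, starting from zero initial state (first sample is 0).
#' @export
#' @examples
#' m <- tf_model(24.70, c(18.60, 37.95))
#' y <- simulate_response(m, rep(0.25, 1000), 5)
#' tail(y, 1)  # approaches the DC value 24.70 * 0.25 = 6.175 bpm
simulate_response <- function(model, u, sample_period_s) {
  stopifnot(inherits(model, "hr_tf"))
  if (!is.numeric(sample_period_s) || length(sample_period_s) != 1L ||
      sample_period_s <= 0) {
    abort("`sample_period_s` must be a single positive number.")
  }
  u <- as.numeric(u)
  if (anyNA(u)) abort("`u` must not contain missing values.")
  if (model$order == 1L) {
    zoh_first_order(u, sample_period_s, model$gain, model$time_constants[1])
  } else {
    zoh_second_order(u, sample_period_s, model$gain,
                     model$time_constants[1], model$time_constants[2])
  }
}
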