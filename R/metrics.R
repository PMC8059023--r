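#' Root-mean-square error between measured and simulated heart rate
#'
#' \deqn{RMSE = \sqrt{\frac{1}{N}\sum_{i=1}^{N} (HR_{sim}(i) - HR(i))^2}}
#' in bpm, over the N samples of the evaluation window.
#'
#' @param hr Measured (detrended) heart-rate deviation, numeric.
#' @param hr_sim Simulated heart-rate deviation of the same length.
#' @return RMSE in bpm.
#' @export
#' @examples
#' compute_rmse(c(1, 2, 3), c(2, 2, 2))  # sqrt(2/3)
compute_rmse <- function(hr, hr_sim) {
  if (length(hr) != length(hr_sim)) {
    abort("`hr` and `hr_sim` must have the same length.")
  }
  if (length(hr) < 1L) abort("Need at least one sample.")
  sqrt(mean((hr_sim - hr)^2))
}

#' Goodness of fit (normalised RMSE, percent)
#'
#' \deqn{fit = \left(1 - \sqrt{\frac{\sum_i (HR(i) - HR_{sim}(i))^2}
#' {\sum_i (HR(i) - \overline{HR})^2}}\right) \times 100}
#' A fit of 100\% is a perfect reproduction; 0\% is no better than
#' predicting the mean; negative values (worse than the mean predictor) are
#' possible and are returned unclipped.
#'
#' @param hr Measured (detrended) heart-rate deviation, numeric,
#'   non-constant.
#' @param hr_sim Simulated heart-rate deviation of the same length.
#' @return Fit in percent.
#' @export
#' @examples
#' compute_fit(c(1, 2, 3), c(1.5, 2, 2.5))  # 50
compute_fit <- function(hr, hr_sim) {
  if (length(hr) != length(hr_sim)) {
    abort("`hr` and `hr_sim` must have the same length.")
  }
  denom <- sqrt(sum((hr - mean(hr))^2))
  if (denom == 0) {
    abort("`hr` is constant: the normalised fit is undefined.")
  }
  (1 - sqrt(sum((hr - hr_sim)^2)) / denom) * 100
}

#' Counterbalanced cross-validation over two sessions
#'
#' For every participant with both sessions, and for every requested model
#' order, estimates the model on one session's preprocessed evaluation
#' segment and validates it on the other session's segment, in both
#' directions (session I estimating / session II validating, then the
#' reverse). Validation simulates the estimated model from zero initial
#' state over the validation window's mean-removed input and scores the
#' detrended measured output with [compute_fit()] and [compute_rmse()].
#' With both orders this produces, per participant, two matched
#' first-/second-order model pairs, so an 11-participant cohort yields 22
#' pairs.
#'
#' @param records Long tibble of raw test records with columns
#'   `participant`, `session` (two distinct labels), `time_s`, `speed_mps`,
#'   `hr_bpm` — e.g. the `records` element of [simulate_cohort()].
#' @param orders Model orders to compare (default `c(1, 2)`).
#' @param window Optional fixed [eval_window()]; selected per record when
#'   `NULL`.
#' @param ... Passed on to [preprocess_record()] and [estimate_tf()].
#' @return A tibble with one row per (participant, estimation session,
#'   order): columns `participant`, `est_session`, `val_session`, `order`,
#'   `gain`, `tau1`, `tau2` (NA for first-order), `rss_est`, `fit_pct`,
#'   `rmse_bpm`.
#' @export
cross_validate <- function(records, orders = c(1L, 2L), window = NULL, ...) {
  orders <- sort(unique(as.integer(orders)))
  if (!all(orders %in% c(1L, 2L))) abort("`orders` must be a subset of {1, 2}.")
  ids <- unique(records$participant)
  out <- list()
  for (id in ids) {
    sub <- records[records$participant == id, , drop = FALSE]
    sessions <- sort(unique(sub$session))
    if (length(sessions) != 2L) {
      warn(sprintf("Participant %s lacks two sessions and is skipped.", id))
      next
    }
    segs <- lapply(sessions, function(s) {
      preprocess_record(sub[sub$session == s, , drop = FALSE],
                        window = window, ...)
    })
    names(segs) <- sessions
    for (es in 1:2) {
      vs <- 3L - es
      est_seg <- segs[[es]]
      val_seg <- segs[[vs]]
      dt <- infer_sample_period(est_seg$time_s)
      for (ord in orders) {
        fit <- estimate_tf(est_seg, order = ord)
        y_sim <- simulate_response(fit$model, val_seg$u_mps, dt)
        tc <- fit$model$time_constants
        out[[length(out) + 1L]] <- tibble::tibble(
          participant = id,
          est_session = sessions[es],
          val_session = sessions[vs],
          order = ord,
          gain = fit$model$gain,
          tau1 = tc[1],
          tau2 = if (ord == 2L) tc[2] else NA_real_,
          rss_est = fit$rss,
          fit_pct = compute_fit(val_seg$y_bpm, y_sim),
          rmse_bpm = compute_rmse(val_seg$y_bpm, y_sim)
        )
      }
    }
  }
  if (length(out) == 0L) abort("No participant had two complete sessions.")
  dplyr::bind_rows(out)
}
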