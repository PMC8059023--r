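#' Paired-outcome plot
#'
#' Shows the validation outcomes of the first- and second-order models as
#' paired samples: one point per model, pairs connected per (participant,
#' estimation session), with the group means drawn as horizontal bars.
#'
#' @param validation Output of [cross_validate()] with both orders.
#' @param outcome `"rmse_bpm"` or `"fit_pct"`.
#' @return A ggplot object.
#' @export
plot_paired_outcomes <- function(validation,
                                 outcome = c("rmse_bpm", "fit_pct")) {
  outcome <- match.arg(outcome)
  df <- validation |>
    dplyr::mutate(
      model = factor(paste0("P", .data$order)),
      pair = interaction(.data$participant, .data$est_session)
    )
  means <- df |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(value = mean(.data[[outcome]]), .groups = "drop")
  ylab <- if (outcome == "rmse_bpm") "RMSE [bpm]" else "fit [%]"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data[[outcome]])) +
    ggplot2::geom_line(ggplot2::aes(group = .data$pair),
                       colour = "darkgreen", alpha = 0.5) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_crossbar(
      data = means,
      ggplot2::aes(y = .data$value, ymin = .data$value, ymax = .data$value),
      width = 0.4, colour = "red"
    ) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal()
}

#' Parameter-dispersion plot
#'
#' Scatter of the estimated gains against each time constant for one model
#' order, with the cohort mean marked by a star and the 95% confidence
#' intervals of the parameter means drawn as a rectangle.
#'
#' @param validation Output of [cross_validate()], or any tibble with
#'   `order`, `gain`, `tau1` (and `tau2`) columns.
#' @param order Which model order to display (default 2).
#' @return A ggplot object.
#' @export
plot_parameter_dispersion <- function(validation, order = 2L) {
  df <- validation[validation$order == order, , drop = FALSE]
  if (nrow(df) < 2L) abort("Need at least 2 models of the requested order.")
  avg <- average_models(df)
  tau_terms <- grep("^tau", avg$summary$term, value = TRUE)
  long <- df |>
    dplyr::select(dplyr::all_of(c("gain", tau_terms))) |>
    tidyr::pivot_longer(dplyr::all_of(tau_terms),
                        names_to = "term", values_to = "tau_s")
  boxes <- avg$summary |>
    dplyr::filter(.data$term %in% tau_terms) |>
    dplyr::rename(tau_lo = "ci_lower", tau_hi = "ci_upper", tau_mean = "mean") |>
    dplyr::mutate(
      gain_lo = avg$summary$ci_lower[avg$summary$term == "gain"],
      gain_hi = avg$summary$ci_upper[avg$summary$term == "gain"],
      gain_mean = avg$summary$mean[avg$summary$term == "gain"]
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tau_s, y = .data$gain)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$term), alpha = 0.7) +
    ggplot2::geom_rect(
      data = boxes, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$tau_lo, xmax = .data$tau_hi,
                   ymin = .data$gain_lo, ymax = .data$gain_hi),
      fill = NA, colour = "grey40"
    ) +
    ggplot2::geom_point(
      data = boxes, inherit.aes = FALSE,
      ggplot2::aes(x = .data$tau_mean, y = .data$gain_mean),
      shape = 8, size = 3, colour = "red"
    ) +
    ggplot2::labs(x = "time constant [s]", y = "gain [bpm/(m/s)]",
                  shape = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn estimate_tf Plot the measured and simulated output deviation
#'   over the estimation window.
#' @param object An `hr_tf_fit`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.hr_tf_fit <- function(object, ...) {
  n <- object$nobs
  df <- tibble::tibble(
    time_s = (seq_len(n) - 1) * object$sample_period_s,
    measured = object$y,
    simulated = object$fitted
  ) |>
    tidyr::pivot_longer(c("measured", "simulated"),
                        names_to = "signal", values_to = "hr_bpm")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$hr_bpm,
                                   colour = .data$signal,
                                   linetype = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [s]", y = "HR deviation [bpm]",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn build_report Paired RMSE and fit panels for the report.
#' @param object An `hr_report`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.hr_report <- function(object, ...) {
  p1 <- plot_paired_outcomes(object$validation, "rmse_bpm")
  p2 <- plot_paired_outcomes(object$validation, "fit_pct")
  list(rmse = p1, fit = p2)
}
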