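#' Paired comparison of first- and second-order validation outcomes
#'
#' Summarises the counterbalanced cross-validation outcomes and tests
#' whether the second-order models outperform the first-order models:
#' a paired one-sided t-test per outcome, on the differences P2 - P1, in
#' the direction of improvement (lower RMSE, higher fit), each with its
#' matching one-sided confidence bound for the mean difference. Normality
#' of each difference set is first assessed with the Lilliefors test; if it
#' is rejected the summary flags the violation and adds a Wilcoxon
#' signed-rank p-value as a distribution-free fallback (reported alongside,
#' not in place of, the t-test).
#'
#' @param validation Output of [cross_validate()] containing both orders.
#' @param alpha Significance level (default 0.05).
#' @param conf_level Confidence level of the one-sided bounds
#'   (default 0.95).
#' @return A tibble with one row per outcome (`rmse_bpm`, `fit_pct`):
#'   columns `outcome`, `n`, `mean_p1`, `sd_p1`, `mean_p2`, `sd_p2`,
#'   `mean_difference` (P2 - P1), `ci_lower`, `ci_upper`, `p_value`,
#'   `direction`, `normality_p`, `normality_ok`, `wilcoxon_p` (NA unless
#'   normality was rejected).
#' @export
compare_orders <- function(validation, alpha = 0.05, conf_level = 0.95) {
  need <- c("participant", "est_session", "order", "fit_pct", "rmse_bpm")
  if (!all(need %in% names(validation))) {
    abort("`validation` must be the output of cross_validate() with both orders.")
  }
  wide <- validation |>
    dplyr::select(dplyr::all_of(c(need))) |>
    tidyr::pivot_wider(names_from = "order",
                       values_from = c("fit_pct", "rmse_bpm"),
                       names_prefix = "p")
  need_wide <- c("fit_pct_p1", "fit_pct_p2", "rmse_bpm_p1", "rmse_bpm_p2")
  if (!all(need_wide %in% names(wide)) || anyNA(wide[need_wide])) {
    abort("Every (participant, estimation session) needs both model orders.")
  }
  outcomes <- tibble::tibble(
    outcome = c("rmse_bpm", "fit_pct"),
    direction = c("less", "greater")
  )
  purrr::pmap_dfr(outcomes, function(outcome, direction) {
    x1 <- wide[[paste0(outcome, "_p1")]]
    x2 <- wide[[paste0(outcome, "_p2")]]
    d <- x2 - x1
    norm <- lilliefors_test(d, alpha = alpha)
    tt <- paired_onesided_ttest(x2, x1, direction = direction,
                                conf_level = conf_level)
    wil <- NA_real_
    if (norm$reject) {
      warn(sprintf(
        "Normality of %s differences rejected (Lilliefors p = %.3g); Wilcoxon fallback reported.",
        outcome, norm$p_value
      ))
      wil <- stats::wilcox.test(d, alternative = direction)$p.value
    }
    tibble::tibble(
      outcome = outcome,
      n = length(d),
      mean_p1 = mean(x1), sd_p1 = sd(x1),
      mean_p2 = mean(x2), sd_p2 = sd(x2),
      mean_difference = tt$mean_difference,
      ci_lower = tt$ci_lower, ci_upper = tt$ci_upper,
      p_value = tt$p_value,
      direction = direction,
      normality_p = norm$p_value,
      normality_ok = !norm$reject,
      wilcoxon_p = wil
    )
  })
}

#' Build the full comparison report
#'
#' Assembles the end products of a model-comparison study: the paired
#' statistical summary of both outcomes ([compare_orders()]), the average
#' transfer function per model order with parameter dispersions
#' ([average_models()]), and the tidy per-model validation table that the
#' plots draw from. No multiple-testing correction is applied across the
#' two outcomes (they are reported as two separate prespecified hypotheses).
#'
#' @param validation Output of [cross_validate()] with both orders.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `hr_report`: a list with `comparison` (the
#'   outcome summary tibble), `average_models` (a named list of
#'   `hr_avg_tf`, one per order), `validation` (the input table) and
#'   `n_participants`.
#' @export
build_report <- function(validation, alpha = 0.05) {
  n_part <- length(unique(validation$participant))
  comparison <- NULL
  if (n_part < 2L) {
    warn("Fewer than 2 participants: the statistical summary is suppressed.")
  } else {
    comparison <- compare_orders(validation, alpha = alpha)
  }
  avgs <- lapply(sort(unique(validation$order)), function(ord) {
    average_models(validation[validation$order == ord, , drop = FALSE])
  })
  names(avgs) <- paste0("P", sort(unique(validation$order)))
  structure(
    list(
      comparison = comparison,
      average_models = avgs,
      validation = validation,
      n_participants = n_part,
      alpha = alpha
    ),
    class = "hr_report"
  )
}

#' @export
print.hr_report <- function(x, digits = 3, ...) {
  cat(sprintf("<hr_report> %d participants, %d validation records\n",
              x$n_participants, nrow(x$validation)))
  if (!is.null(x$comparison)) {
    cat("\nOutcome comparison (P2 - P1, paired one-sided tests):\n")
    print(x$comparison, digits = digits)
  }
  for (nm in names(x$average_models)) {
    cat(sprintf("\nAverage %s model (n = %d):\n", nm, x$average_models[[nm]]$n))
    print(x$average_models[[nm]]$model, digits = digits)
  }
  invisible(x)
}

#' @export
tidy.hr_report <- function(x, ...) {
  if (is.null(x$comparison)) {
    abort("The report has no statistical summary (fewer than 2 participants).")
  }
  x$comparison
}

#' @export
glance.hr_report <- function(x, ...) {
  tibble::tibble(
    n_participants = x$n_participants,
    n_records = nrow(x$validation),
    orders = paste(sort(unique(x$validation$order)), collapse = ","),
    alpha = x$alpha
  )
}
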