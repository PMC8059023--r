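#' Lilliefors test of composite normality
#'
#' Kolmogorov-Smirnov test against a normal distribution whose mean and
#' standard deviation are estimated from the sample, with the Lilliefors
#' correction of the null distribution for that estimation. Used as the
#' gate before the paired t-tests: the parametric comparison is reported
#' only when normality of the paired differences is not rejected.
#'
#' @param x Numeric sample, n >= 4, non-constant.
#' @param alpha Significance level for the reported decision (default 0.05).
#' @return A tibble with columns `statistic`, `p_value`, `reject` (logical,
#'   at `alpha`) and `n`.
#' @export
lilliefors_test <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  if (length(x) < 4L) abort("The Lilliefors test requires at least 4 observations.")
  if (sd(x) == 0) abort("The sample is constant: normality is degenerate.")
  res <- nortest::lillie.test(x)
  tibble::tibble(
    statistic = unname(res$statistic),
    p_value = res$p.value,
    reject = res$p.value < alpha,
    n = length(x)
  )
}

#' Paired one-sided t-test
#'
#' Tests whether the mean of the paired differences `x2 - x1` is greater
#' than (direction `"greater"`) or less than (direction `"less"`) zero,
#' returning the t statistic, the one-sided p-value, the mean difference,
#' and the matching one-sided 95% confidence bound for the mean difference.
#'
#' @param x2,x1 Paired numeric samples of equal length (n >= 2); the test is
#'   on `d = x2 - x1`.
#' @param direction `"greater"` or `"less"`: the alternative hypothesis for
#'   the mean of `d`.
#' @param conf_level Confidence level of the one-sided interval
#'   (default 0.95).
#' @return A tibble with columns `mean_difference`, `t`, `df`, `p_value`,
#'   `ci_lower`, `ci_upper` (one of the bounds infinite) and `n`.
#' @export
#' @examples
#' paired_onesided_ttest(c(2, 3, 4), c(1, 1, 1), "greater")
paired_onesided_ttest <- function(x2, x1, direction = c("greater", "less"),
                                  conf_level = 0.95) {
  direction <- match.arg(direction)
  if (length(x2) != length(x1)) abort("`x2` and `x1` must be paired (equal length).")
  d <- as.numeric(x2) - as.numeric(x1)
  if (length(d) < 2L) abort("Need at least 2 pairs.")
  if (sd(d) == 0) abort("All paired differences are equal: the t-test is degenerate.")
  res <- t.test(d, alternative = direction, conf.level = conf_level)
  tibble::tibble(
    mean_difference = unname(res$estimate),
    t = unname(res$statistic),
    df = unname(res$parameter),
    p_value = res$p.value,
    ci_lower = res$conf.int[1],
    ci_upper = res$conf.int[2],
    n = length(d)
  )
}

#' One-sided confidence interval for a mean
#'
#' Half-infinite t interval for the mean of `x`: `(-Inf, m + t_q * se]` for
#' direction `"less"` or `[m - t_q * se, +Inf)` for direction `"greater"`,
#' with `t_q` the `level` quantile of the t distribution on n - 1 degrees of
#' freedom. By test-interval duality the bound excludes 0 exactly when the
#' corresponding one-sided t-test rejects at `1 - level`.
#'
#' @param x Numeric sample (n >= 2, non-constant), typically paired
#'   differences.
#' @param level Confidence level (default 0.95).
#' @param direction Direction of the matching alternative hypothesis:
#'   `"greater"` gives a lower bound, `"less"` an upper bound.
#' @return Length-2 numeric `c(lower, upper)` with one infinite endpoint.
#' @export
one_sided_mean_ci <- function(x, level = 0.95,
                              direction = c("greater", "less")) {
  direction <- match.arg(direction)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) abort("Need at least 2 observations.")
  if (sd(x) == 0) abort("The sample is constant: the interval is degenerate.")
  se <- sd(x) / sqrt(n)
  q <- qt(level, df = n - 1)
  if (direction == "greater") {
    c(mean(x) - q * se, Inf)
  } else {
    c(-Inf, mean(x) + q * se)
  }
}

#' Power of the paired one-sided t-test
#'
#' Computes the power of a one-sided paired t-test for a standardised mean
#' difference `d` (mean of paired differences over their SD) at sample size
#' `n`, via the noncentral-t distribution; or, when `power` is given instead
#' of `n`, the sample size required to reach it.
#'
#' @param d Standardised effect size of the paired differences.
#' @param n Number of pairs (omit to solve for it).
#' @param power Target power (omit to solve for it).
#' @param alpha One-sided significance level (default 0.05).
#' @return A tibble with columns `d`, `n`, `alpha`, `power`.
#' @export
#' @examples
#' paired_power(d = 0.8, n = 11)
#' paired_power(d = 0.8, power = 0.8)  # required n
paired_power <- function(d, n = NULL, power = NULL, alpha = 0.05) {
  if (is.null(n) == is.null(power)) {
    abort("Supply exactly one of `n` and `power`.")
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  if (!is.null(power) && (power <= 0 || power >= 1)) {
    abort("`power` must lie in (0, 1).")
  }
  if (is.null(power) && d == 0) {
    # degenerate null case: rejection probability equals the level
    return(tibble::tibble(d = 0, n = n, alpha = alpha, power = alpha))
  }
  res <- power.t.test(n = n, delta = abs(d), sd = 1, sig.level = alpha,
                      power = power, type = "paired",
                      alternative = "one.sided")
  tibble::tibble(d = d, n = res$n, alpha = alpha, power = res$power)
}

#' Average model over a cohort of fitted transfer functions
#'
#' Averages the individual gains and time constants of same-order models to
#' give the cohort's representative transfer function, together with the
#' dispersion (SD) and two-sided 95% confidence intervals of the means for
#' each parameter.
#'
#' @param models A list of [tf_model()] / [hr_tf_fit()][estimate_tf]
#'   objects, or a tibble with columns `gain`, `tau1` (and `tau2` for order
#'   2) such as the output of [cross_validate()] filtered to one order.
#' @param conf_level Confidence level of the parameter means (default 0.95).
#' @return An object of class `hr_avg_tf`: a list with `model` (the average
#'   [tf_model()]), `summary` (a tibble of per-parameter mean, sd, CI) and
#'   `n`.
#' @export
average_models <- function(models, conf_level = 0.95) {
  par_tbl <- if (is.data.frame(models)) {
    tb <- tibble::as_tibble(models)
    if (!"gain" %in% names(tb) || !"tau1" %in% names(tb)) {
      abort("`models` must provide `gain` and `tau1` columns.")
    }
    ords <- if ("order" %in% names(tb)) unique(tb$order) else
      if ("tau2" %in% names(tb) && all(!is.na(tb$tau2))) 2L else 1L
    if (length(ords) != 1L) abort("All models must have the same order.")
    keep <- c("gain", "tau1", if (ords == 2L) "tau2")
    tb[keep]
  } else {
    ms <- lapply(models, function(m) if (inherits(m, "hr_tf_fit")) m$model else m)
    if (!all(vapply(ms, inherits, logical(1), "hr_tf"))) {
      abort("`models` must be hr_tf or hr_tf_fit objects, or a parameter tibble.")
    }
    ords <- unique(vapply(ms, `[[`, integer(1), "order"))
    if (length(ords) != 1L) abort("All models must have the same order.")
    dplyr::bind_rows(lapply(ms, function(m) {
      tc <- m$time_constants
      tibble::tibble(gain = m$gain, tau1 = tc[1],
                     tau2 = if (ords == 2L) tc[2] else NULL)
    }))
  }
  n <- nrow(par_tbl)
  if (n < 2L) abort("Averaging requires at least 2 models.")
  if (anyNA(par_tbl)) abort("Parameter table contains missing values.")
  q <- qt(1 - (1 - conf_level) / 2, df = n - 1)
  summ <- purrr::map_dfr(names(par_tbl), function(nm) {
    v <- par_tbl[[nm]]
    m <- mean(v); s <- sd(v)
    tibble::tibble(term = nm, mean = m, sd = s,
                   ci_lower = m - q * s / sqrt(n),
                   ci_upper = m + q * s / sqrt(n))
  })
  avg <- tf_model(summ$mean[summ$term == "gain"],
                  summ$mean[grepl("^tau", summ$term)])
  structure(list(model = avg, summary = summ, n = n), class = "hr_avg_tf")
}

#' @export
print.hr_avg_tf <- function(x, ...) {
  cat(sprintf("<hr_avg_tf> average of %d models\n", x$n))
  print(x$model)
  print(x$summary)
  invisible(x)
}

#' @export
tidy.hr_avg_tf <- function(x, ...) {
  x$summary
}
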