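test_that("zero-SD populations reproduce the population means exactly", {
  pop <- population_spec(age_sd = 0, gain_sd = 0, tau_sds = c(0, 0),
                         hr_baseline_sd = 0)
  set.seed(1)
  p <- draw_participants(pop, 1)[[1]]
  expect_equal(p$model$gain, 24.70)
  expect_equal(p$model$time_constants, c(18.60, 37.95))
  expect_equal(p$age, 32.5)
  expect_equal(p$hr_ref, 0.765 * (220 - 32.5))
})

test_that("participant draws are reproducible from the seed", {
  pop <- population_spec()
  set.seed(99)
  a <- draw_participants(pop, 3)
  set.seed(99)
  b <- draw_participants(pop, 3)
  expect_identical(a, b)
})

test_that("sample means of many draws sit within 3 standard errors", {
  pop <- population_spec()
  set.seed(5)
  # wide treadmill limits so the operating-speed validity redraw never
  # triggers and the raw sampling scheme itself is what is checked; the
  # 0.1x-mean positivity truncation sits >4 SD below every mean, so its
  # bias is negligible against a 3-SE band
  ps <- draw_participants(pop, 10000, treadmill_limits = c(-1e6, 1e6))
  # closed-form mean of a normal truncated below at 0.1x its mean
  trunc_mean <- function(mu, s) {
    z <- (0.1 * mu - mu) / s
    mu + s * stats::dnorm(z) / (1 - stats::pnorm(z))
  }
  for (extract in list(
    list(function(p) p$model$gain, pop$gain_mean, pop$gain_sd),
    list(function(p) p$age, pop$age_mean, pop$age_sd),
    list(function(p) p$hr_baseline, pop$hr_baseline_mean, pop$hr_baseline_sd)
  )) {
    v <- vapply(ps, extract[[1]], numeric(1))
    expect_lt(abs(mean(v) - trunc_mean(extract[[2]], extract[[3]])),
              3 * sd(v) / sqrt(length(v)))
  }
  # time constants are drawn independently but stored sorted (Phase I <=
  # Phase II), so their means are those of the min/max of the pair;
  # brute-force oracle from plain truncated-normal draws
  rtr <- function(n, mu, s) {
    x <- rnorm(n, mu, s)
    while (any(bad <- x < 0.1 * mu)) x[bad] <- rnorm(sum(bad), mu, s)
    x
  }
  a <- rtr(2e5, pop$tau_means[1], pop$tau_sds[1])
  b <- rtr(2e5, pop$tau_means[2], pop$tau_sds[2])
  t1 <- vapply(ps, function(p) p$model$time_constants[1], numeric(1))
  t2 <- vapply(ps, function(p) p$model$time_constants[2], numeric(1))
  expect_lt(abs(mean(t1) - mean(pmin(a, b))), 4 * sd(t1) / sqrt(length(t1)))
  expect_lt(abs(mean(t2) - mean(pmax(a, b))), 4 * sd(t2) / sqrt(length(t2)))
})

test_that("the target heart rate follows factor * (220 - age)", {
  expect_equal(hr_ref(20), 153)
  expect_equal(hr_ref(20, factor = 0.7), 140)
  expect_error(hr_ref(220), "between 0 and 220")
  expect_error(hr_ref(0), "between 0 and 220")
  expect_error(hr_ref(30, factor = 1), "between 0 and 1")
})

test_that("the operating speed solves the affine steady-state relation", {
  p <- quiet_participant(tf_model(24.70, c(18.60, 37.95)),
                         hr_baseline = 80, v_m = 2.5)
  expect_equal(p$hr_ref, 141.75)
  expect_equal(operating_speed(p), 2.5)
  # hr_ref equal to baseline puts the operating point at zero speed
  p0 <- participant_profile("P", 30, tf_model(24.70, c(18.60, 37.95)),
                            hr_baseline = 120, hr_ref = 120)
  expect_equal(operating_speed(p0, treadmill_limits = NULL), 0)
  expect_error(operating_speed(p0), "treadmill limits")
  # doubling the gain halves the speed
  p2 <- participant_profile("P", 30, tf_model(2 * 24.70, c(18.60, 37.95)),
                            hr_baseline = 80, hr_ref = 141.75)
  expect_equal(operating_speed(p2), 1.25)
})

test_that("noise-free simulation matches the dense-grid ODE oracle", {
  skip_if_not_installed("deSolve")
  p <- quiet_participant()
  spec <- prbs_spec(2)
  prof <- speed_profile(prbs_bits(spec, 10), spec, 1, 600)
  rec <- simulate_test(p, prof, v_m = 2)
  udev <- prof$speed_mps - 2
  expect_equal(rec$hr_bpm - (80 + 24.70 * 2),
               ode_oracle(p$model, udev, 1),
               tolerance = 1e-7)
})

test_that("constant speed at the operating point holds HR at HRref", {
  p <- quiet_participant(v_m = 2)
  prof <- tibble::tibble(time_s = 0:599, speed_mps = 2)
  rec <- simulate_test(p, prof, v_m = 2)
  expect_true(all(abs(rec$hr_bpm - p$hr_ref) < 1e-12))
})

test_that("doubling the noise SDs doubles the residual about the clean trace", {
  base <- quiet_participant()
  spec <- prbs_spec(2)
  prof <- speed_profile(prbs_bits(spec, 36), spec, 1, 2160)
  clean <- simulate_test(base, prof, v_m = 2)$hr_bpm
  sd_resid <- function(hrv, meas, seed) {
    p <- participant_profile("P01", 30, base$model, hr_baseline = 80,
                             hr_ref = base$hr_ref,
                             drift_rate_bpm_per_min = 0,
                             hrv_sd = hrv, measurement_noise_sd = meas)
    set.seed(seed)
    reps <- replicate(8, sd(simulate_test(p, prof, v_m = 2)$hr_bpm - clean))
    mean(reps)
  }
  r1 <- sd_resid(2, 1, 11)
  r2 <- sd_resid(4, 2, 11)
  expect_equal(r2 / r1, 2, tolerance = 0.1)
})

test_that("linear drift is removed exactly by the detrending step", {
  p <- participant_profile("P01", 30, tf_model(24.70, c(18.60, 37.95)),
                           hr_baseline = 80, hr_ref = 129.4,
                           drift_rate_bpm_per_min = 2,
                           hrv_sd = 0, measurement_noise_sd = 0)
  spec <- prbs_spec(2)
  prof <- speed_profile(prbs_bits(spec, 36), spec, 1, 2160)
  with_drift <- simulate_test(p, prof, v_m = 2)
  no_drift <- simulate_test(quiet_participant(v_m = 2), prof, v_m = 2)
  a <- preprocess_record(with_drift)
  b <- preprocess_record(no_drift)
  expect_equal(a$y_bpm, b$y_bpm, tolerance = 1e-10)
})

test_that("cohort simulation produces two 1-Hz sessions per participant", {
  coh <- simulate_cohort(n_participants = 2, seed = 3, duration_s = 600)
  expect_identical(nrow(coh$participants), 2L)
  counts <- dplyr::count(coh$records, participant, session)
  expect_identical(nrow(counts), 4L)
  expect_true(all(counts$n == 600L))
  expect_true(all(coh$records$hr_bpm > 0))
  # reproducibility from the master seed
  coh2 <- simulate_cohort(n_participants = 2, seed = 3, duration_s = 600)
  expect_equal(coh$records, coh2$records)
})
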