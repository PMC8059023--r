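test_that("block averaging reduces 1 Hz to 0.2 Hz", {
  expect_equal(downsample_hr(tibble::tibble(time_s = 0:4, hr_bpm = 1:5))$hr_bpm, 3)
  const <- downsample_hr(tibble::tibble(time_s = 0:99, hr_bpm = rep(7, 100)))
  expect_true(all(const$hr_bpm == 7))
  expect_equal(infer_sample_period(const$time_s), 5)
  long <- downsample_hr(tibble::tibble(time_s = 0:1799, hr_bpm = rnorm(1800)))
  expect_identical(nrow(long), 360L)
  expect_message(
    downsample_hr(tibble::tibble(time_s = 0:12, hr_bpm = rnorm(13))),
    "trailing"
  )
  expect_error(downsample_hr(tibble::tibble(time_s = numeric(), hr_bpm = numeric())),
               "empty")
})

test_that("window extraction slices exactly N aligned samples", {
  dat <- tibble::tibble(time_s = seq(0, 2155, by = 5), hr_bpm = rnorm(432))
  w <- eval_window(290, 2085, 5)
  expect_identical(w$n_samples, 360L)
  expect_identical(nrow(extract_window(dat, w)), 360L)
  # full-span window is the identity
  full <- eval_window(0, 2155, 5)
  expect_equal(extract_window(dat, full), dat)
  expect_error(extract_window(dat, eval_window(2000, 3000, 5)), "provides")
  expect_error(extract_window(dat, eval_window(292, 2087, 5)), "grid")
  shifted <- dplyr::mutate(dat, time_s = time_s * 2)
  expect_error(extract_window(shifted, w), "period")
})

test_that("detrending removes any straight line exactly and is idempotent", {
  tt <- seq(0, 100, by = 5)
  for (ab in list(c(0, 0), c(70, 0.3), c(-4, -1.2))) {
    d <- detrend_output(tibble::tibble(time_s = tt, hr_bpm = ab[1] + ab[2] * tt))
    expect_equal(d$y_bpm, rep(0, length(tt)), tolerance = 1e-10)
  }
  set.seed(2)
  noisy <- tibble::tibble(time_s = tt, hr_bpm = rnorm(length(tt)))
  once <- detrend_output(noisy)
  twice <- detrend_output(dplyr::mutate(once, hr_bpm = y_bpm))
  expect_equal(twice$y_bpm, once$y_bpm, tolerance = 1e-12)
  # residuals are orthogonal to the constant and to time
  expect_lt(abs(sum(once$y_bpm)), 1e-9)
  expect_lt(abs(sum(once$y_bpm * (tt - mean(tt)))), 1e-7)
  expect_error(detrend_output(tibble::tibble(time_s = 0:1, hr_bpm = c(1, 2))),
               "at least 3")
})

test_that("an outlier on a line leaves its leverage-weighted projection residual", {
  # 5-point hand computation: y = line + e5 on the last point; the residual
  # vector is (I - H) %*% (0,0,0,0,e5) with H the hat matrix of [1, t]
  tt <- c(0, 1, 2, 3, 4)
  e <- c(0, 0, 0, 0, 2.5)
  X <- cbind(1, tt)
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  expected <- as.numeric((diag(5) - H) %*% e)
  d <- detrend_output(tibble::tibble(time_s = tt, hr_bpm = 10 + 3 * tt + e))
  expect_equal(d$y_bpm, expected, tolerance = 1e-10)
})

test_that("input mean removal maps balanced windows to exactly +/- amplitude", {
  bal <- tibble::tibble(time_s = seq(0, 55, 5),
                        speed_mps = rep(c(2.25, 1.75), 6))
  out <- remove_mean_input(bal)
  expect_setequal(unique(out$u_mps), c(-0.25, 0.25))
  const <- remove_mean_input(tibble::tibble(time_s = 0:5, speed_mps = rep(2, 6)))
  expect_true(all(const$u_mps == 0))
  # 2:1 imbalance at +/-0.25: deviations split the 0.5 m/s swing 1/3 : 2/3
  imb <- remove_mean_input(tibble::tibble(time_s = 0:2,
                                          speed_mps = c(2.25, 2.25, 1.75)))
  expect_equal(sort(unique(imb$u_mps)), c(-2 / 3 * 0.5, 1 / 3 * 0.5))
})

test_that("short heart-rate gaps are interpolated, long ones rejected", {
  rec <- tibble::tibble(time_s = 0:9, hr_bpm = c(80, 81, NA, NA, 84, 85, 86, 87, 88, 89))
  expect_message(filled <- fill_missing_hr(rec), "Interpolated")
  expect_equal(filled$hr_bpm[3:4], c(82, 83))
  long_gap <- tibble::tibble(time_s = 0:9,
                             hr_bpm = c(80, NA, NA, NA, NA, 85, 86, 87, 88, 89))
  expect_error(fill_missing_hr(long_gap), "exceeds")
  edge <- tibble::tibble(time_s = 0:3, hr_bpm = c(NA, 81, 82, 83))
  expect_error(fill_missing_hr(edge), "boundary")
})

test_that("downsample and window commute when the window aligns to 5-s blocks", {
  set.seed(4)
  rec <- tibble::tibble(time_s = 0:2159, speed_mps = rep(2, 2160),
                        hr_bpm = 130 + rnorm(2160))
  w <- eval_window(290, 2085, 5)
  a <- extract_window(downsample_hr(rec), w)
  # windowing first at 1 Hz over the same span, then downsampling
  w1 <- eval_window(290, 2089, 1)
  b <- downsample_hr(extract_window(rec, w1))
  expect_equal(a$hr_bpm, b$hr_bpm, tolerance = 1e-12)
})

test_that("the preprocessing chain emits a zero-mean, trend-free segment", {
  coh <- simulate_cohort(n_participants = 1, seed = 8)
  rec <- coh$records[coh$records$session == "I", ]
  seg <- preprocess_record(rec)
  expect_identical(nrow(seg), 360L)
  expect_identical(names(seg), c("time_s", "u_mps", "y_bpm"))
  expect_lt(abs(mean(seg$y_bpm)), 1e-9)
  expect_lt(abs(mean(seg$u_mps)), 1e-12)
  expect_setequal(round(unique(seg$u_mps), 10), c(-0.25, 0.25))
  w <- attr(seg, "window")
  expect_equal(w$start_time_s, 290)
  expect_equal(w$end_time_s, 2085)
})
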