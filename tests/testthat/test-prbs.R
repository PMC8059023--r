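test_that("maximal-length sequences have period 2^order - 1 for orders 2-6", {
  taps <- list(c(2, 1), c(3, 2), c(4, 3), c(5, 3), c(6, 5))
  orders <- 2:6
  for (i in seq_along(orders)) {
    m <- orders[i]
    spec <- prbs_spec(2, register_order = m, feedback_taps = taps[[i]],
                      initial_state = rep(1L, m))
    per <- 2^m - 1
    bits <- prbs_bits(spec, 2L * per)
    expect_identical(bits[1:per], bits[(per + 1):(2 * per)])
    # brute-force cycle detection: no circular shift below the full period
    shorter <- vapply(seq_len(per - 1), function(k) {
      all(bits[1:per] == bits[c((k + 1):per, 1:k)])
    }, logical(1))
    expect_false(any(shorter))
  }
})

test_that("one order-5 period is balanced with 16 ones and 15 zeros", {
  bits <- prbs_bits(prbs_spec(2), 31)
  expect_identical(sum(bits == 1L), 16L)
  expect_identical(sum(bits == 0L), 15L)
})

test_that("the +/-1 mapped period has the two-valued circular autocorrelation", {
  x <- 2 * prbs_bits(prbs_spec(2), 31) - 1
  ac <- vapply(0:30, function(k) sum(x * x[((0:30 + k) %% 31) + 1]), numeric(1))
  expect_equal(ac[1], 31)
  expect_true(all(ac[-1] == -1))
})

test_that("non-maximal tap sets are rejected with a diagnostic", {
  expect_error(prbs_bits(prbs_spec(2, feedback_taps = c(5, 1)), 10),
               "not maximal-length")
  expect_error(prbs_bits(prbs_spec(2, feedback_taps = c(5, 4)), 10),
               "not maximal-length")
})

test_that("spec construction validates its invariants", {
  expect_error(prbs_spec(2, initial_state = rep(0L, 5)), "all zero")
  expect_error(prbs_spec(2, register_order = 1), "at least 2")
  expect_error(prbs_spec(2, half_amplitude = -0.1), "positive")
})

test_that("speed profiles take exactly the two levels v_m +/- amplitude", {
  prof <- default_profile_5s(mean_speed = 2)
  expect_setequal(unique(prof$speed_mps), c(1.75, 2.25))
  expect_equal(diff(range(diff(prof$time_s))), 0)
})

test_that("each bit is held for clock/sample consecutive samples", {
  spec <- prbs_spec(2)
  prof <- speed_profile(c(1L, 0L, 1L), spec, sample_period_s = 5,
                        duration_s = 180)
  runs <- rle(prof$speed_mps)
  expect_identical(runs$lengths, rep(12L, 3))  # 60 s / 5 s
  # all-ones input gives a constant profile at mean + amplitude
  const <- speed_profile(rep(1L, 5), spec, 5, 300)
  expect_true(all(const$speed_mps == 2.25))
})

test_that("profile construction is idempotent on the same grid and validates inputs", {
  spec <- prbs_spec(2)
  bits <- prbs_bits(spec, 36)
  p1 <- speed_profile(bits, spec, 5, 2160)
  p2 <- speed_profile(bits, spec, 5, 2160)
  expect_identical(p1, p2)
  expect_error(speed_profile(bits, spec, 7, 300), "integer multiple")
  expect_error(speed_profile(bits, spec, 5, 36 * 60 + 5), "exceeds")
})

test_that("the default design yields the 290-2085 s window with 180/180 balance", {
  prof <- default_profile_5s()
  w <- select_balanced_window(prof)
  expect_equal(w$start_time_s, 290)
  expect_equal(w$end_time_s, 2085)
  expect_identical(w$n_samples, 360L)
  seg <- extract_window(prof, w)
  expect_identical(sum(seg$speed_mps == 2.25), 180L)
  expect_identical(sum(seg$speed_mps == 1.75), 180L)
})

test_that("any returned window satisfies the equal-count invariant exactly", {
  spec <- prbs_spec(1.5, initial_state = c(1L, 0L, 1L, 1L, 0L))
  prof <- speed_profile(prbs_bits(spec, 36), spec, 5, 2160)
  for (n in c(120L, 240L, 360L)) {
    w <- select_balanced_window(prof, n_samples = n, offset_s = 100)
    seg <- extract_window(prof, w)
    expect_identical(sum(seg$speed_mps > 1.5), n %/% 2L)
  }
})

test_that("alternating bits give a balanced window; one-level profiles cannot", {
  spec <- prbs_spec(2)
  alt <- speed_profile(rep(c(1L, 0L), 18), spec, 5, 2160)
  w <- select_balanced_window(alt, n_samples = 24L, offset_s = 0)
  expect_equal(w$start_time_s, 0)
  allhigh <- tibble::tibble(time_s = seq(0, 995, by = 5),
                            speed_mps = rep(2.25, 200))
  expect_error(select_balanced_window(allhigh, 100L, 0), "two speed levels")
  # two levels present but far too few lows: closest imbalance is reported
  lop <- tibble::tibble(time_s = seq(0, 995, by = 5),
                        speed_mps = c(rep(2.25, 199), 1.75))
  expect_error(select_balanced_window(lop, 100L, 0), "closest imbalance")
})
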