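# Shared fixtures: default excitation design and independent oracles.

# default 5th-order PRBS design about 2 m/s, sampled at 5 s for 2160 s
default_profile_5s <- function(mean_speed = 2) {
  spec <- prbs_spec(mean_speed = mean_speed)
  speed_profile(prbs_bits(spec, 36), spec, sample_period_s = 5,
                duration_s = 2160)
}

# input deviation over the balanced evaluation window of the default design
balanced_u <- function(mean_speed = 2) {
  prof <- default_profile_5s(mean_speed)
  w <- select_balanced_window(prof)
  seg <- extract_window(prof, w)
  list(window = w, time_s = seg$time_s,
       u = seg$speed_mps - mean(seg$speed_mps))
}

# dense-grid ODE oracle for the ZOH response of a first/second-order model,
# independent of the package's discretisation path
ode_oracle <- function(model, u, dt) {
  n <- length(u)
  k <- model$gain
  step_u <- function(t) u[min(floor(t / dt + 1e-12) + 1, n)]
  if (model$order == 1L) {
    tau <- model$time_constants[1]
    deriv <- function(t, x, p) list((-x[1] + k * step_u(t)) / tau)
    x0 <- 0
  } else {
    t1 <- model$time_constants[1]
    t2 <- model$time_constants[2]
    deriv <- function(t, x, p) {
      list(c((-x[1] + step_u(t)) / t1, (-x[2] + k * x[1]) / t2))
    }
    x0 <- c(0, 0)
  }
  sol <- deSolve::lsoda(x0, (seq_len(n) - 1) * dt, deriv, NULL,
                        rtol = 1e-11, atol = 1e-12, hmax = dt / 2)
  sol[, ncol(sol)]
}

# brute-force outcome oracles (independent re-implementation of the metric
# formulas, summed term by term)
brute_rmse <- function(hr, hr_sim) {
  acc <- 0
  for (i in seq_along(hr)) acc <- acc + (hr_sim[i] - hr[i])^2
  sqrt(acc / length(hr))
}
brute_fit <- function(hr, hr_sim) {
  num <- 0; den <- 0; m <- sum(hr) / length(hr)
  for (i in seq_along(hr)) {
    num <- num + (hr[i] - hr_sim[i])^2
    den <- den + (hr[i] - m)^2
  }
  (1 - sqrt(num) / sqrt(den)) * 100
}

# noise-free participant with the cohort-average second-order dynamics
quiet_participant <- function(model = tf_model(24.70, c(18.60, 37.95)),
                              hr_baseline = 80, v_m = 2) {
  participant_profile(
    "P01", age = 30, model = model, hr_baseline = hr_baseline,
    hr_ref = hr_baseline + model$gain * v_m,
    drift_rate_bpm_per_min = 0, hrv_sd = 0, measurement_noise_sd = 0
  )
}
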