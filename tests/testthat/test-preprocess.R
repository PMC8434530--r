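test_that("linear resampling preserves linear signals and duration", {
  t8 <- (0:79) / 8
  expect_equal(resample_linear(t8, 8, 10), (0:99) / 10)
  x <- rnorm(50)
  expect_identical(resample_linear(x, 10, 10), x)
})

test_that("8->10 Hz resampling error is bounded by the dense-grid oracle", {
  f <- 0.25
  t8 <- (0:800) / 8                          # last input beyond last output
  x8 <- sin(2 * pi * f * t8)
  y <- resample_linear(x8, 8, 10)
  t10 <- (seq_along(y) - 1) / 10
  # oracle: worst-case linear-interpolation error of the 8 Hz samples,
  # found by brute-force dense evaluation of the interpolant
  td <- seq(0, max(t8), by = 1e-3)
  dense_err <- max(abs(approx(t8, x8, xout = td)$y - sin(2 * pi * f * td)))
  expect_lt(max(abs(y - sin(2 * pi * f * t10))), dense_err + 1e-12)
})

test_that("energy rate screening matches direct summation", {
  n <- 600
  zero <- polygraph_record(numeric(n), rnorm(n), rnorm(n), 10)
  q <- quality_pass(zero, threshold = 1e-6)
  expect_false(q$pass)
  expect_equal(unname(q$energy_rate["airflow"]), 0)

  s <- sin(2 * pi * 0.25 * (0:5999) / 10)
  rec <- polygraph_record(s, s, s, 10)
  q2 <- quality_pass(rec, threshold = 0.1)
  expect_equal(unname(q2$energy_rate["thoracic"]), 5.0, tolerance = 1e-3)
  expect_true(q2$pass)
  expect_true(quality_pass(zero, threshold = 0)$pass)
})

test_that("energy scaling follows the closed form", {
  expect_error(scale_signal(rep(3, 100)), "degenerate")
  x <- rep(c(2, -2), 50)                     # zero-mean, |x| = 2
  y <- scale_signal(x, A = 0.5)
  expect_equal(attr(y, "SF"), 0.5 / 4)
  expect_equal(as.numeric(y), x * 0.125)
  s <- sin(2 * pi * 0.25 * (0:9999) / 10)    # 250 periods of unit sine
  ys <- scale_signal(s, A = 0.5)
  expect_equal(attr(ys, "SF"), 1.0, tolerance = 0.01)
  expect_equal(max(abs(ys)), 1.0, tolerance = 0.01)
})

test_that("energy scaling is inverse-homogeneous in amplitude", {
  x <- rnorm(500)
  for (k in c(0.1, 2, 17)) {
    expect_equal(as.numeric(scale_signal(k * x)),
                 as.numeric(scale_signal(x)) / k)
  }
})

test_that("zero-phase low-pass passes breathing and rejects noise bands", {
  t <- (0:5999) / 10
  expect_equal(lowpass_zero_phase(numeric(1000)), numeric(1000))
  # oracle: squared analog Butterworth magnitude |H(f)|^2 = (1+(f/fc)^16)^-1
  # applied twice (forward-backward)
  pass <- lowpass_zero_phase(sin(2 * pi * 0.25 * t))
  gain_pass <- max(abs(pass[1000:5000]))
  expect_gte(gain_pass, 0.99)
  hi <- lowpass_zero_phase(0.8 * sin(2 * pi * 4.5 * t + 0.3))
  expect_lte(max(abs(hi[1000:5000])) / 0.8, 1e-4)
  expect_error(lowpass_zero_phase(rnorm(10)), "warm-up")
})

test_that("zero-phase filtering introduces no delay", {
  t <- (0:2999) / 10
  x <- sin(2 * pi * 0.2 * t) * (1 + 0.3 * sin(2 * pi * 0.01 * t))
  y <- lowpass_zero_phase(x)
  cc <- vapply(-20:20, function(l) sdbdetect:::ncc_at_lag(y, x, l), 0)
  expect_equal((-20:20)[which.max(cc)], 0)
})

test_that("phase alignment recovers constructed delays against thoracic", {
  t <- (0:5999) / 10
  env <- 1 + 0.3 * sin(2 * pi * 0.013 * t)
  base <- env * sin(2 * pi * 0.25 * t)
  delayed <- c(rep(0, 15), base[1:(length(base) - 15)])   # +1.5 s delay
  rec <- polygraph_record(base, base, delayed, 10)
  al <- align_phases(rec, max_lag_s = 5)
  expect_equal(unname(al$lags_s["abdominal"]), -1.5)
  expect_equal(unname(al$lags_s["airflow"]), 0)
  ov <- 100:5800
  expect_equal(al$aligned$abdominal[ov], base[ov], tolerance = 1e-9)
  # identical channels: all zero lags
  al0 <- align_phases(polygraph_record(base, base, base, 10), 5)
  expect_equal(unname(al0$lags_s), c(0, 0, 0))
})

test_that("lags beyond the search bound are clamped and flagged", {
  # aperiodic band-limited signal, so the in-range correlation peak sits
  # at the boundary nearest the true 8 s lag
  base <- withr::with_seed(8, lowpass_zero_phase(rnorm(6000), cutoff_hz = 0.1))
  delayed <- c(rep(0, 80), base[1:(length(base) - 80)])   # true lag 8 s
  al <- align_phases(polygraph_record(base, base, delayed, 10),
                     max_lag_s = 5)
  expect_true(al$at_bound[["abdominal"]])
  expect_lte(abs(al$lags_s[["abdominal"]]), 5)
})

test_that("alignment is idempotent", {
  sim <- generate_record(sim_config(duration_s = 300, n_apnea = 2,
                                    n_hypopnea = 1, seed = 13))
  pre <- prepare_record(sim)
  al2 <- align_phases(pre$record, 5)
  expect_equal(unname(al2$lags_s), c(0, 0, 0))
})

test_that("the full preprocessing chain resamples to the working rate", {
  sim <- generate_record(sim_config(duration_s = 120, sample_rate_hz = 8,
                                    n_apnea = 1, n_hypopnea = 0,
                                    episode_duration_range_s = c(12, 20),
                                    channel_lags_s = c(0, 0, 0), seed = 3))
  pre <- preprocess_record(sim$record, preprocess_config(align = FALSE))
  expect_equal(pre$sample_rate_hz, 10)
  expect_equal(pre$duration_s, 120)
})
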