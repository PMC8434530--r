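test_that("zero-crossing counts match the analytic sine count", {
  for (f in c(0.2, 0.25, 0.4)) {
    t <- (0:(600 * 10 - 1)) / 10
    zc <- zero_crossings(sin(2 * pi * f * t + 0.1))
    expect_lte(abs(length(zc) - 2 * f * 600), 1)
  }
  expect_length(zero_crossings(rep(1, 100)), 0)
  expect_equal(zero_crossings(rep(c(1, -1), 5)), 2:10)
})

test_that("exact zeros attach to the preceding segment", {
  x <- c(1, 1, 0, 0, -1, -1)
  expect_equal(zero_crossings(x), 5L)        # segment flips at the -1
})

test_that("segment energy follows the scaled closed form", {
  expect_equal(segment_energy(c(2, 2)), 2.0)
  expect_equal(segment_energy(c(1, 0, 1)), 2 / 9)
  x <- rnorm(17)
  expect_equal(segment_energy(2 * x), 4 * segment_energy(x))
  expect_error(segment_energy(numeric(0)), "empty")
})

test_that("segment energy matches direct summation on random segments", {
  withr::local_seed(31)
  for (i in 1:50) {
    x <- rnorm(sample(1:40, 1))
    acc <- 0
    for (v in x) acc <- acc + abs(v)^2
    expect_equal(segment_energy(x), acc / length(x)^2, tolerance = 1e-14)
  }
})

test_that("minimal-energy signal takes the per-breath channel minimum", {
  t <- (0:(120 * 10 - 1)) / 10
  a <- sin(2 * pi * 0.25 * t)
  rec <- polygraph_record(a, 0.5 * a, 2 * a, 10)
  me <- minimal_energy_signal(rec)
  expect_length(me, ceiling(length(a) / 5))
  expect_equal(max(me), 1)
  expect_true(all(me >= 0))
  # oracle: recompute fills segment by segment; thoracic (x0.5) is the
  # minimum everywhere since energies scale with amplitude^2
  zc <- zero_crossings(a)
  bounds <- c(1, zc, length(a) + 1)
  fill10 <- numeric(length(a))
  for (k in seq_len(length(bounds) - 1)) {
    idx <- bounds[k]:(bounds[k + 1] - 1)
    fill10[idx] <- min(segment_energy(a[idx]), segment_energy(0.5 * a[idx]),
                       segment_energy(2 * a[idx]))
  }
  expect_equal(me, (fill10 / max(fill10[seq(1, length(a), 5)]))[
    seq(1, length(a), 5)])
})

test_that("minimal-energy signal is invariant to common rescaling", {
  sim <- generate_record(sim_config(duration_s = 200, n_apnea = 1,
                                    n_hypopnea = 1, seed = 17))
  rec <- sim$record
  rec2 <- polygraph_record(3 * rec$airflow, 3 * rec$thoracic,
                           3 * rec$abdominal, 10)
  expect_equal(minimal_energy_signal(rec), minimal_energy_signal(rec2))
})

test_that("an all-zero record yields a zero signal with a warning", {
  rec <- polygraph_record(numeric(500), numeric(500), numeric(500), 10)
  expect_warning(me <- minimal_energy_signal(rec), "all-zero")
  expect_equal(me, numeric(100))
})

test_that("stage-2 windows have the 64 x 4 geometry and end-point labels", {
  n <- 120                                     # 60 s at 2 Hz
  inputs <- cbind(P_N = rep(0.8, n), P_A = rep(0.1, n),
                  P_Hb = rep(0.1, n), min_energy = runif(n))
  ann <- data.frame(class = c("hypopnea", "apnea"),
                    start_s = c(35, 50), end_s = c(48, 60))
  ws <- make_windows_stage2(inputs, ann)
  expect_equal(dim(ws$x), c(57, 4, 64))        # (60-32)/0.5 + 1
  expect_equal(ws$time_s, seq(32, 60, by = 0.5))
  expect_equal(as.character(ws$labels[ws$time_s == 40]), "H")
  expect_equal(as.character(ws$labels[ws$time_s == 55]), "A")
  # half-open: a window ending exactly at the episode end is normal
  expect_equal(as.character(ws$labels[ws$time_s == 48]), "N")
})

test_that("stage-2 labels agree with a point-in-interval oracle", {
  withr::local_seed(23)
  for (rep in 1:20) {
    ann <- random_annotations(300, n_events = sample(0:6, 1))
    n <- 600
    inputs <- matrix(runif(4 * n), n, 4)
    ws <- make_windows_stage2(inputs, ann)
    oracle <- vapply(ws$time_s, bf_label_stage2, "", annotations = ann)
    expect_identical(as.character(ws$labels), oracle)
  }
})

test_that("stage-2 inputs are padded onto the energy grid", {
  p <- matrix(1 / 3, 50, 3)
  tl <- prob_timeline(seq(0, by = 0.5, length.out = 50), p,
                      c("N", "A", "Hb"))
  inputs <- stage2_inputs(tl, runif(80))
  expect_equal(dim(inputs), c(80, 4))
  expect_equal(unname(inputs[70, "P_N"]), 1 / 3)
  expect_error(make_windows_stage2(inputs[, 1:3], NULL), "4 series")
})

test_that("stage-2 prediction stamps probabilities at window ends", {
  n <- 100
  inputs <- cbind(runif(n), runif(n), runif(n), runif(n))
  model <- train_lstm(array(rnorm(10 * 4 * 64), c(10, 4, 64)),
                      rep(c("N", "A", "H"), length.out = 10),
                      net_config(lstm_units = 4, dense_units = 4,
                                 epochs = 1, batch_size = 4, seed = 1),
                      classes = c("N", "A", "H"))
  tl <- predict_timeline_stage2(inputs, model)
  expect_equal(tl$time_s[1], 32)
  expect_equal(nrow(tl$probs), n - 64 + 1)
  expect_equal(rowSums(tl$probs), rep(1, nrow(tl$probs)), tolerance = 1e-9)
})
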