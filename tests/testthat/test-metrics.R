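test_that("AI/HI/REI are event counts per recording hour", {
  ep <- data.frame(class = c(rep("apnea", 7), rep("hypopnea", 5)),
                   start_s = 1:12 * 1000, end_s = 1:12 * 1000 + 20)
  idx <- compute_indices(ep, trt_h = 6)
  expect_equal(idx$AI, 7 / 6, tolerance = 1e-12)
  expect_equal(idx$HI, 5 / 6, tolerance = 1e-12)
  expect_equal(idx$REI, 2.0)
  expect_equal(compute_indices(ep[0, ], 6)$REI, 0)
  expect_error(compute_indices(ep, 0), "TRT")
})

test_that("severity classes respect the 5/15/30 boundaries", {
  expect_equal(as.character(severity_class(c(0, 4.99, 5, 14.99, 15, 17,
                                             29.99, 30, 80))),
               c("Normal", "Normal", "Mild", "Mild", "Moderate",
                 "Moderate", "Moderate", "Severe", "Severe"))
})

test_that("epoch confusion is exact for identical annotation sets", {
  ann <- data.frame(class = c("apnea", "hypopnea"),
                    start_s = c(20, 60), end_s = c(35, 80))
  cm <- epoch_confusion(ann, ann, duration_s = 120)
  expect_equal(unname(diag(cm$normalized)), c(1, 1, 1))
  expect_equal(cm$total_accuracy, 1.0)
  expect_equal(sum(cm$counts), 240)
})

test_that("a one-second shift misplaces exactly two grid points per edge", {
  truth <- data.frame(class = "apnea", start_s = 20, end_s = 30)
  pred <- data.frame(class = "apnea", start_s = 21, end_s = 31)
  cm <- epoch_confusion(pred, truth, duration_s = 60)
  expect_equal(cm$counts["A", "A"], 18)      # 18 of 20 apnea points hit
  expect_equal(cm$counts["A", "N"], 2)       # 20.0, 20.5 missed
  expect_equal(cm$counts["N", "A"], 2)       # 30.0, 30.5 spurious
  expect_equal(unname(cm$per_class_accuracy["A"]), 0.9)
  # row sums conserve true-class point counts
  expect_equal(unname(rowSums(cm$counts)), c(100, 0, 20))
})

test_that("a record with no annotations is all-normal and fully correct", {
  none <- data.frame(class = character(0), start_s = numeric(0),
                     end_s = numeric(0))
  cm <- epoch_confusion(none, none, duration_s = 30)
  expect_equal(cm$total_accuracy, 1.0)
  expect_equal(unname(cm$counts["N", "N"]), 60)
})

test_that("confusion aggregation sums counts before normalizing", {
  ann <- data.frame(class = "apnea", start_s = 0, end_s = 10)
  none <- ann[0, ]
  c1 <- epoch_confusion(ann, ann, 20)
  c2 <- epoch_confusion(none, ann, 20)       # misses everything
  agg <- combine_confusions(list(c1, c2))
  expect_equal(unname(agg$counts["A", "A"]), 20)
  expect_equal(unname(agg$counts["A", "N"]), 20)
  expect_equal(unname(agg$normalized["A", "A"]), 0.5)
})

test_that("index error statistics match closed forms", {
  x <- c(1, 5, 9, 3)
  s0 <- rei_error_stats(x, x)
  expect_equal(s0$MAE, 0); expect_equal(s0$SD, 0)
  expect_equal(s0$pearson_r, 1); expect_equal(s0$spearman_r, 1)
  s3 <- rei_error_stats(x + 3, x)
  expect_equal(s3$MAE, 3); expect_equal(s3$SD, 0)
  expect_equal(s3$pearson_r, 1)
  expect_equal(s3$min_err, 3); expect_equal(s3$max_err, 3)
})

test_that("error statistics agree with independent formula evaluation", {
  pred <- c(12.4, 3.1, 28.0, 7.7)
  true <- c(10.0, 5.2, 25.1, 9.9)
  s <- rei_error_stats(pred, true)
  err <- pred - true
  expect_equal(s$MAE, sum(abs(err)) / 4)
  expect_equal(s$SD, sqrt(sum((err - mean(err))^2) / 3))
  expect_equal(s$min_err, min(err)); expect_equal(s$max_err, max(err))
  expect_equal(s$pearson_r,
               sum((pred - mean(pred)) * (true - mean(true))) /
                 sqrt(sum((pred - mean(pred))^2) *
                        sum((true - mean(true))^2)))
  expect_equal(s$spearman_r, cor(rank(pred), rank(true)))
  # Spearman is invariant under monotone transforms
  expect_equal(rei_error_stats(exp(pred), true^3)$spearman_r, s$spearman_r)
  # fewer than two pairs: correlations undefined
  expect_true(is.na(rei_error_stats(1, 2)$pearson_r))
})

test_that("wake exclusion rules handle containment and straddling", {
  wake <- data.frame(start_s = 100, end_s = 200)
  eps <- data.frame(class = "apnea",
                    start_s = c(120, 300, 90, 185),
                    end_s = c(150, 330, 108, 230))
  # fully inside -> removed; outside -> kept; straddling with midpoint
  # outside -> kept under the default rule
  kept <- exclude_wake(eps, wake)
  expect_equal(kept$start_s, c(300, 90, 185))
  expect_equal(exclude_wake(eps, wake, rule = "overlap")$start_s, 300)
  expect_equal(exclude_wake(eps, wake, rule = "inside")$start_s,
               c(300, 90, 185))
  expect_equal(nrow(exclude_wake(eps[0, ], wake)), 0)
})
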