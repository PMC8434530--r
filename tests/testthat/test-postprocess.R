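nah_timeline <- function(probs) {
  prob_timeline(seq(0, by = 0.5, length.out = nrow(probs)), probs,
                c("N", "A", "H"))
}

test_that("episode borders follow argmax changes and A/H does not split", {
  # argmax: N N A A H H N, equal A/H shares and equal mean probabilities
  p <- rbind(c(0.8, 0.1, 0.1), c(0.8, 0.1, 0.1),
             c(0.2, 0.6, 0.2), c(0.2, 0.6, 0.2),
             c(0.2, 0.2, 0.6), c(0.2, 0.2, 0.6),
             c(0.8, 0.1, 0.1))
  ep <- extract_episodes(nah_timeline(p))
  expect_equal(nrow(ep), 1)
  expect_equal(ep$start_s, 1.0)
  expect_equal(ep$end_s, 3.0)
  expect_equal(ep$class, "apnea")            # exact tie -> apnea
  expect_equal(ep$certainty, mean(c(0.6, 0.6, 0.2, 0.2)))
  expect_equal(ep$mean_N_prob, 0.2)
})

test_that("an all-normal timeline yields no episodes", {
  p <- matrix(rep(c(0.9, 0.05, 0.05), 20), ncol = 3, byrow = TRUE)
  expect_equal(nrow(extract_episodes(nah_timeline(p))), 0)
})

test_that("certainty is the mean assigned-class probability", {
  p <- rbind(c(0.9, 0.05, 0.05), c(0.1, 0.8, 0.1), c(0.05, 0.9, 0.05),
             c(0.9, 0.05, 0.05))
  ep <- extract_episodes(nah_timeline(p))
  expect_equal(ep$certainty, 0.85)
})

test_that("majority ties break toward the higher mean class probability", {
  p <- rbind(c(0.1, 0.5, 0.4), c(0.1, 0.4, 0.5))  # 1 A point, 1 H point
  ep <- extract_episodes(nah_timeline(p))
  expect_equal(ep$class, "apnea")                 # equal means -> apnea
  p2 <- rbind(c(0.1, 0.45, 0.45), c(0.05, 0.4, 0.55))
  expect_equal(extract_episodes(nah_timeline(p2))$class, "hypopnea")
})

test_that("extraction matches the brute-force scanner on random timelines", {
  withr::local_seed(19)
  for (rep in 1:60) {
    tl <- random_timeline(sample(10:80, 1))
    expect_equal(extract_episodes(tl), bf_extract_episodes(tl$time_s,
                                                           tl$probs),
                 ignore_attr = TRUE)
  }
})

test_that("the clinical 10 s duration filter is inclusive", {
  ep <- data.frame(start_s = c(0, 20, 50), end_s = c(9.5, 30, 65),
                   class = "apnea", certainty = 1, mean_N_prob = 0)
  kept <- filter_min_duration(ep)
  expect_equal(kept$start_s, c(20, 50))
  expect_equal(nrow(filter_min_duration(ep[0, ])), 0)
})

test_that("threshold optimization finds the RMSE-zero band (smallest tie)", {
  eps <- data.frame(start_s = seq(0, 900, by = 100)[1:10],
                    end_s = seq(0, 900, by = 100)[1:10] + 20,
                    class = "hypopnea",
                    certainty = rep(c(0.6, 0.4), each = 5),
                    mean_N_prob = 0.9)
  truth <- data.frame(class = rep("hypopnea", 5),
                      start_s = 1:5 * 100, end_s = 1:5 * 100 + 20)
  ts <- optimize_thresholds(list(eps), list(truth), trt_h = 1,
                            additional_marking = FALSE)
  expect_equal(ts$H_thr, 0.42)   # first grid point keeping exactly 5 events
  # perfect certainties: smallest grid value wins the tie
  eps2 <- eps[1:5, ]; eps2$certainty <- 1
  ts2 <- optimize_thresholds(list(eps2), list(truth), trt_h = 1,
                             additional_marking = FALSE)
  expect_equal(ts2$H_thr, 0)
  ts3 <- optimize_thresholds(list(eps2), list(truth), trt_h = 1, grid = 0,
                             additional_marking = FALSE)
  expect_equal(ts3$H_thr, 0)
  expect_error(optimize_thresholds(list(eps), list(truth), 1,
                                   grid = numeric(0)), "empty")
})

test_that("sub-10 s episodes are excluded from threshold determination", {
  # five real (20 s) events at certainty 0.6 plus five short (5 s) ones at
  # 0.9; the short ones must not lure the threshold upward
  eps <- data.frame(start_s = seq(0, 900, by = 100)[1:10],
                    end_s = c(seq(0, 400, by = 100) + 20,
                              seq(500, 900, by = 100) + 5),
                    class = "apnea",
                    certainty = rep(c(0.6, 0.9), each = 5),
                    mean_N_prob = 0.9)
  truth <- data.frame(class = rep("apnea", 5),
                      start_s = 1:5 * 100, end_s = 1:5 * 100 + 20)
  ts <- optimize_thresholds(list(eps), list(truth), trt_h = 1,
                            additional_marking = FALSE)
  expect_equal(ts$A_thr, 0)      # all five >=10 s events already match truth
})

test_that("optimization equals an exhaustive independent grid search", {
  withr::local_seed(37)
  grid <- seq(0, 1, by = 0.02)
  n_rec <- 3
  eps <- lapply(1:n_rec, function(i) {
    k <- sample(5:12, 1)
    data.frame(start_s = seq_len(k) * 60, end_s = seq_len(k) * 60 + 15,
               class = sample(c("apnea", "hypopnea"), k, replace = TRUE),
               certainty = runif(k), mean_N_prob = runif(k))
  })
  truth <- lapply(1:n_rec, function(i) random_annotations(3600, 5))
  trt <- rep(1, n_rec)
  ts <- optimize_thresholds(eps, truth, trt, grid = grid,
                            additional_marking = FALSE)
  for (cls in c("apnea", "hypopnea")) {
    rmse <- vapply(grid, function(th) {
      pred <- vapply(1:n_rec, function(i) {
        e <- eps[[i]]
        e <- e[e$class == cls & e$end_s - e$start_s >= 10 &
                 e$certainty >= th, ]
        nrow(e) / trt[i]
      }, 0)
      tru <- vapply(1:n_rec, function(i) {
        a <- truth[[i]]
        nrow(a[a$class == cls & a$end_s - a$start_s >= 10, ]) / trt[i]
      }, 0)
      sqrt(mean((pred - tru)^2))
    }, 0)
    got <- if (cls == "apnea") ts$A_thr else ts$H_thr
    expect_equal(got, grid[which.min(rmse)])
  }
})

test_that("raising a threshold never increases the surviving count", {
  withr::local_seed(51)
  eps <- data.frame(start_s = 1:30 * 40, end_s = 1:30 * 40 + 15,
                    class = "apnea", certainty = runif(30),
                    mean_N_prob = runif(30))
  counts <- vapply(seq(0, 1, 0.1), function(a)
    nrow(apply_thresholds(eps, threshold_set(a, 0.5),
                          additional_marking = FALSE)), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("low-N episodes are reinstated with their majority class", {
  thr <- threshold_set(0.5, 0.5)
  expect_equal(thr$N_thr, 0.5)
  eps <- data.frame(start_s = c(0, 50, 100), end_s = c(20, 70, 120),
                    class = c("apnea", "apnea", "apnea"),
                    certainty = c(0.9, 0.45, 0.45),
                    mean_N_prob = c(0.05, 0.05, 0.8))
  out <- apply_thresholds(eps, thr)
  expect_equal(out$start_s, c(0, 50))        # 0.45/0.8 dropped
  expect_equal(out$reinstated, c(FALSE, TRUE))
  off <- apply_thresholds(eps, thr, additional_marking = FALSE)
  expect_equal(off$start_s, 0)
})
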