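# Brute-force reference implementations used to cross-check the vectorized
# pipeline code. These deliberately use naive per-point loops.

# Per-window stage-1 label by explicit grid-point enumeration.
bf_label_stage1 <- function(start, annotations, window_s = 16,
                            stride_s = 0.5, hb_range = c(4, 12)) {
  hypo <- annotations[annotations$class == "hypopnea", , drop = FALSE]
  for (o in hypo$start_s)
    if (o >= start + hb_range[1] && o <= start + hb_range[2]) return("Hb")
  pts <- seq(start, start + window_s - stride_s, by = stride_s)
  cls <- vapply(pts, function(t) {
    for (k in seq_len(nrow(annotations))) {
      if (t >= annotations$start_s[k] && t < annotations$end_s[k])
        return(annotations$class[k])
    }
    "none"
  }, "")
  if (all(cls == "none")) return("N")
  if (all(cls == "apnea")) return("A")
  NA_character_
}

# Stage-2 label of one window end point.
bf_label_stage2 <- function(end_s, annotations) {
  for (k in seq_len(nrow(annotations))) {
    if (end_s >= annotations$start_s[k] && end_s < annotations$end_s[k])
      return(switch(annotations$class[k], apnea = "A", hypopnea = "H", "N"))
  }
  "N"
}

# Smoothing oracle: for each grid point collect every window covering it
# and average their probability vectors.
bf_smooth <- function(probs, window_samples = 32) {
  n <- nrow(probs)
  out <- probs
  for (t in seq_len(n)) {
    cover <- max(1, t - window_samples + 1):t
    out[t, ] <- colMeans(probs[cover, , drop = FALSE])
  }
  out
}

# Episode extraction oracle: scan grid points one by one.
bf_extract_episodes <- function(time_s, probs) {
  am <- apply(probs, 1, which.max)
  out <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    class = character(0), certainty = numeric(0),
                    mean_N_prob = numeric(0))
  i <- 1
  n <- length(am)
  while (i <= n) {
    if (am[i] == 1) { i <- i + 1; next }
    j <- i
    while (j < n && am[j + 1] != 1) j <- j + 1
    idx <- i:j
    n_a <- sum(am[idx] == 2); n_h <- sum(am[idx] == 3)
    cls <- if (n_a > n_h) "apnea" else if (n_h > n_a) "hypopnea"
           else if (mean(probs[idx, 3]) > mean(probs[idx, 2])) "hypopnea"
           else "apnea"
    out <- rbind(out, data.frame(
      start_s = time_s[i], end_s = time_s[j] + 0.5, class = cls,
      certainty = mean(probs[idx, if (cls == "apnea") 2 else 3]),
      mean_N_prob = mean(probs[idx, 1])))
    i <- j + 1
  }
  out
}

# Random half-open, non-overlapping annotation set on [0, duration).
random_annotations <- function(duration_s, n_events = 4) {
  if (n_events == 0)
    return(data.frame(class = character(0), start_s = numeric(0),
                      end_s = numeric(0)))
  starts <- sort(runif(n_events, 0, duration_s - 12))
  out <- data.frame(class = sample(c("apnea", "hypopnea"), n_events,
                                   replace = TRUE),
                    start_s = starts,
                    end_s = pmin(starts + runif(n_events, 10, 40),
                                 duration_s))
  # enforce non-overlap by clipping at the next start
  if (n_events > 1)
    out$end_s[-n_events] <- pmin(out$end_s[-n_events], out$start_s[-1])
  out[out$end_s - out$start_s >= 10, , drop = FALSE]
}

# Random probability timeline over (N, A, H).
random_timeline <- function(n, sticky = 0.8) {
  cls <- integer(n)
  cls[1] <- sample(3, 1)
  for (i in seq_len(n)[-1])
    cls[i] <- if (runif(1) < sticky) cls[i - 1] else sample(3, 1)
  p <- matrix(runif(3 * n, 0.05, 0.3), n, 3)
  p[cbind(seq_len(n), cls)] <- runif(n, 0.5, 1)
  p <- p / rowSums(p)
  prob_timeline(seq(0, by = 0.5, length.out = n), p, c("N", "A", "H"))
}
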