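# Stage 1: 16 s / 0.5 s-stride windows over the three 10 Hz channels,
# labelled N (normal throughout), A (apnea throughout) or Hb (a hypopnea
# onset 4-12 s after the window start). Hb is the key labelling idea: the
# >=30% amplitude drop that defines a hypopnea is only visible at its
# onset, so the first network detects onsets rather than whole episodes.

#' Windowed training/inference set
#'
#' Windows are stored as one numeric array `x` of shape
#' `(n_windows, n_channels, n_timesteps)` plus per-window labels and
#' reference times, instead of a list of matrices, so they feed the network
#' without copying.
#'
#' @param x Window array.
#' @param labels Character/factor vector (or `NULL` for inference sets).
#' @param time_s Per-window reference time: window start for stage 1,
#'   window end for stage 2.
#' @param classes The full class set labels may take.
#' @return An object of class `window_set`.
#' @export
window_set <- function(x, labels, time_s, classes) {
  stopifnot(is.array(x), length(dim(x)) == 3,
            is.null(labels) || length(labels) == dim(x)[1],
            length(time_s) == dim(x)[1])
  structure(list(x = x,
                 labels = if (is.null(labels)) NULL
                          else factor(as.character(labels), levels = classes),
                 time_s = time_s, classes = classes),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<window_set> %d windows of %d x %d", d[1], d[3], d[2]))
  if (!is.null(x$labels)) {
    tb <- table(x$labels)
    cat(" |", paste(sprintf("%s: %d", names(tb), tb), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Extract one window as a time-by-channel matrix
#'
#' @param ws A [window_set()].
#' @param i Window index.
#' @return Matrix of `n_timesteps x n_channels` (160 x 3 for stage 1,
#'   64 x 4 for stage 2).
#' @export
window_matrix <- function(ws, i) t(ws$x[i, , , drop = TRUE])

#' Concatenate window sets
#'
#' @param sets List of compatible [window_set()] objects.
#' @return A single [window_set()].
#' @export
bind_window_sets <- function(sets) {
  sets <- Filter(function(s) dim(s$x)[1] > 0, sets)
  if (!length(sets)) stop("no windows to bind")
  d <- dim(sets[[1]]$x)
  n <- sum(vapply(sets, function(s) dim(s$x)[1], 0L))
  x <- array(0, c(n, d[2], d[3]))
  off <- 0L
  for (s in sets) {
    k <- dim(s$x)[1]
    x[(off + 1):(off + k), , ] <- s$x
    off <- off + k
  }
  window_set(x,
             if (is.null(sets[[1]]$labels)) NULL
             else unlist(lapply(sets, function(s) as.character(s$labels))),
             unlist(lapply(sets, function(s) s$time_s)),
             sets[[1]]$classes)
}

# Extract per-window channel data at 10 Hz: array (n_windows, 3, 160),
# per-window per-channel mean removed.
extract_stage1_data <- function(record, starts_s, window_s = 16) {
  fs <- record$sample_rate_hz
  spw <- round(window_s * fs)
  s_idx <- round(starts_s * fs) + 1L
  idx <- outer(0:(spw - 1L), s_idx, `+`)
  x <- array(0, c(length(starts_s), 3, spw))
  for (d in seq_along(CHANNELS)) {
    m <- matrix(record[[CHANNELS[d]]][idx], nrow = spw)
    m <- sweep(m, 2, colMeans(m))
    x[, d, ] <- t(m)
  }
  x
}

stage1_starts <- function(duration_s, window_s = 16, stride_s = 0.5) {
  if (duration_s < window_s) return(numeric(0))
  seq(0, duration_s - window_s, by = stride_s)
}

#' Build the stage-1 labelled window set
#'
#' Windows of 16 s with 0.5 s stride over the preprocessed 10 Hz record.
#' A window is labelled `N` when every 0.5 s grid point it covers is
#' unannotated, `A` when every grid point lies inside an apnea annotation,
#' and `Hb` when a hypopnea onset falls in `[start + 4, start + 12]`
#' (inclusive bounds). Windows matching none of these rules are discarded;
#' a window matching the `Hb` rule takes that label regardless of its
#' coverage, since onset detection is the purpose of the class.
#'
#' @param record Preprocessed [polygraph_record()] at 10 Hz.
#' @param annotations Episode data.frame (`class`, `start_s`, `end_s`).
#' @param window_s,stride_s Window geometry (seconds).
#' @param hb_range_s Onset offset bounds defining `Hb`, seconds after
#'   window start.
#' @return A [window_set()] with classes `N`, `A`, `Hb` and `time_s` equal
#'   to window starts; empty (with a warning) if the record is shorter than
#'   one window.
#' @export
make_windows_stage1 <- function(record, annotations, window_s = 16,
                                stride_s = 0.5, hb_range_s = c(4, 12)) {
  starts <- stage1_starts(record$duration_s, window_s, stride_s)
  if (!length(starts)) {
    warning("record shorter than one window; no stage-1 windows")
    return(window_set(array(0, c(0, 3, round(window_s *
                                               record$sample_rate_hz))),
                      character(0), numeric(0), STAGE1_CLASSES))
  }
  lab <- label_windows_stage1(starts, annotations, window_s, stride_s,
                              hb_range_s)
  keep <- !is.na(lab)
  x <- extract_stage1_data(record, starts[keep], window_s)
  window_set(x, lab[keep], starts[keep], STAGE1_CLASSES)
}

# Vectorized stage-1 labelling; NA = discarded. Kept separate so tests can
# compare it against a brute-force per-point enumerator.
label_windows_stage1 <- function(starts, annotations, window_s = 16,
                                 stride_s = 0.5, hb_range_s = c(4, 12)) {
  ppw <- round(window_s / stride_s)         # grid points per window
  apnea <- annotations[annotations$class == "apnea", , drop = FALSE]
  hypo <- annotations[annotations$class == "hypopnea", , drop = FALSE]
  n <- length(starts)
  lab <- rep(NA_character_, n)
  if (!n) return(lab)

  # class of each 0.5 s grid point covered by any window
  tg <- seq(starts[1], starts[n] + window_s - stride_s, by = stride_s)
  in_a <- point_in_intervals(tg, apnea)
  in_h <- point_in_intervals(tg, hypo)
  ca <- cumsum(in_a)
  cany <- cumsum(in_a | in_h)
  k <- seq_len(n)                            # window k covers points k..k+ppw-1
  n_a <- ca[k + ppw - 1L] - c(0, ca)[k]
  n_any <- cany[k + ppw - 1L] - c(0, cany)[k]
  lab[n_any == 0L] <- "N"
  lab[n_a == ppw] <- "A"

  # Hb: hypopnea onset within [start + hb_min, start + hb_max]
  for (o in hypo$start_s) {
    hit <- starts >= o - hb_range_s[2] & starts <= o - hb_range_s[1]
    lab[hit] <- "Hb"
  }
  lab
}

#' Balance classes by random undersampling
#'
#' Randomly keeps an equal number of windows per class, equal to the size
#' of the least represented class (optionally capped), so the training set
#' is balanced. Selection is uniform at random and reproducible per seed.
#'
#' @param ws A labelled [window_set()].
#' @param seed Integer seed for the selection.
#' @param max_per_class Optional cap on the per-class count (used to bound
#'   training cost on large corpora).
#' @return The balanced [window_set()].
#' @export
balance_classes <- function(ws, seed = 1L, max_per_class = Inf) {
  if (is.null(ws$labels)) stop("window set has no labels")
  counts <- table(ws$labels)
  absent <- names(counts)[counts == 0]
  if (length(absent))
    stop("cannot balance: class '", absent[1], "' has no windows")
  m <- min(min(counts), max_per_class)
  keep <- with_seed(seed, {
    unlist(lapply(levels(ws$labels), function(cl) {
      idx <- which(ws$labels == cl)
      if (length(idx) > m) sample(idx, m) else idx
    }))
  })
  keep <- sort(keep)
  window_set(ws$x[keep, , , drop = FALSE], ws$labels[keep],
             ws$time_s[keep], ws$classes)
}

#' Train the stage-1 network
#'
#' @param ws Balanced stage-1 [window_set()].
#' @param config A [net_config()]; the stage-1 default trains for 50
#'   epochs.
#' @return An `sdb_lstm` model over classes `N`, `A`, `Hb`.
#' @export
train_stage1 <- function(ws, config = net_config(epochs = 50)) {
  train_lstm(ws$x, ws$labels, config, classes = STAGE1_CLASSES)
}

#' Class-probability timeline
#'
#' A per-class probability series on the 0.5 s grid: the inter-stage
#' representation of the pipeline.
#'
#' @param time_s Grid times (0.5 s step).
#' @param probs `T x n_classes` matrix; rows must sum to 1 (tolerance
#'   1e-6).
#' @param classes Column class names.
#' @return Object of class `prob_timeline`.
#' @export
prob_timeline <- function(time_s, probs, classes) {
  probs <- as.matrix(probs)
  stopifnot(length(time_s) == nrow(probs), ncol(probs) == length(classes))
  if (nrow(probs) && max(abs(rowSums(probs) - 1)) > 1e-6)
    stop("probability rows must sum to 1")
  colnames(probs) <- classes
  structure(list(time_s = time_s, probs = probs, classes = classes,
                 grid_hz = 2), class = "prob_timeline")
}

#' @export
print.prob_timeline <- function(x, ...) {
  cat(sprintf("<prob_timeline> %d points at %g Hz, classes: %s\n",
              nrow(x$probs), x$grid_hz, paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Predict the raw stage-1 probability timeline
#'
#' Runs the stage-1 network on every 16 s window (0.5 s stride) and lines
#' the class probabilities up at the window start times.
#'
#' @param record Preprocessed [polygraph_record()] at 10 Hz.
#' @param model Stage-1 `sdb_lstm`.
#' @param window_s Window length, seconds.
#' @return A [prob_timeline()] over `N`, `A`, `Hb`.
#' @export
predict_timeline_stage1 <- function(record, model, window_s = 16) {
  starts <- stage1_starts(record$duration_s, window_s)
  if (!length(starts)) stop("record shorter than one stage-1 window")
  x <- extract_stage1_data(record, starts, window_s)
  prob_timeline(starts, predict(model, x), model$classes)
}

#' Moving-average smoothing of a probability timeline
#'
#' Applies a trailing moving average of `window_samples` grid steps (32
#' samples = 16 s at 2 Hz) with shrinking support at the start, so that
#' each smoothed sample is the mean probability of every stage-1 window
#' whose 16 s span contains that time. Row sums are preserved and constant
#' timelines are unchanged.
#'
#' @param timeline A [prob_timeline()].
#' @param window_samples Average length in grid steps.
#' @return Smoothed [prob_timeline()].
#' @export
smooth_timeline <- function(timeline, window_samples = 32) {
  p <- timeline$probs
  n <- nrow(p)
  if (n == 0) return(timeline)
  cs <- apply(p, 2, cumsum)
  lo <- pmax(seq_len(n) - window_samples, 0L)       # exclusive lower index
  cnt <- seq_len(n) - lo
  sm <- (cs[seq_len(n), , drop = FALSE] -
           rbind(0, cs)[lo + 1L, , drop = FALSE]) / cnt
  prob_timeline(timeline$time_s, sm, timeline$classes)
}
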