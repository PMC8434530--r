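# Stage 2: the smoothed N/A/Hb probabilities are joined with a
# "minimal energy" breath-by-breath signal and re-windowed (32 s, 0.5 s
# stride -> 64 x 4 samples) for the second network, which outputs the
# final N/A/H probabilities. The minimal-energy signal carries the
# information the first stage lacks: where a hypopnea ends.

#' Zero crossings of the airflow signal
#'
#' Returns the 1-based indices at which a new sign segment starts, i.e.
#' positions `i` such that the sign at `i` differs from the sign at
#' `i - 1`. Exact zeros inherit the preceding sign, so they attach to the
#' preceding segment.
#'
#' @param airflow Zero-mean numeric vector.
#' @return Integer vector of segment-start indices (possibly empty for a
#'   single-sign signal).
#' @export
zero_crossings <- function(airflow) {
  n <- length(airflow)
  s <- sign(airflow)
  nz <- which(s != 0)
  if (!length(nz)) return(integer(0))
  last_nz <- cummax(ifelse(s != 0, seq_len(n), 0L))
  last_nz[last_nz == 0L] <- nz[1]          # leading zeros take first sign
  filled <- s[last_nz]
  which(filled[-1] != filled[-n]) + 1L
}

#' Scaled energy of a breath segment
#'
#' `E = sum(|x(n)|^2) / N^2` over the `N` samples between two consecutive
#' airflow zero crossings. The `N^2` scaling makes slow deep breaths and
#' short shallow ones comparable.
#'
#' @param series_segment Numeric vector (one inspiration or expiration).
#' @return Scalar energy, >= 0.
#' @export
segment_energy <- function(series_segment) {
  if (!length(series_segment)) stop("empty segment")
  sum(series_segment^2) / length(series_segment)^2
}

#' Minimal-energy breath signal
#'
#' Partitions the recording at airflow zero crossings into single
#' inspirations/expirations; per segment the scaled energy is computed on
#' each of the three channels and the space between crossings is filled
#' with the lowest of the three values. The 10 Hz piecewise-constant series
#' is downsampled to 2 Hz by decimation (every 5th sample; the series is
#' constant within breaths, so no anti-alias filter is applied) and
#' normalized by its maximum.
#'
#' @param record Preprocessed [polygraph_record()] at 10 Hz.
#' @return Numeric vector at 2 Hz in `[0, 1]`, length
#'   `ceiling(n_samples / 5)`; all zeros (with a warning) for an all-zero
#'   record.
#' @export
minimal_energy_signal <- function(record) {
  n <- length(record$airflow)
  bounds <- c(1L, zero_crossings(record$airflow), n + 1L)
  len <- diff(bounds)
  fill <- rep(Inf, length(len))
  for (ch in CHANNELS) {
    cs <- c(0, cumsum(record[[ch]]^2))
    e <- (cs[bounds[-1]] - cs[bounds[-length(bounds)]]) / len^2
    fill <- pmin(fill, e)
  }
  series10 <- rep(fill, len)
  series2 <- series10[seq(1, n, by = 5)]
  mx <- max(series2)
  if (mx == 0) {
    warning("all-zero record: minimal-energy signal is zero")
    return(series2)
  }
  series2 / mx
}

#' Assemble the four stage-2 input series on a common 2 Hz grid
#'
#' The smoothed stage-1 timeline ends one window length before the record
#' does (its last entry sits at the last window start), while the
#' minimal-energy signal spans the whole recording; the probability rows
#' are therefore extended by repeating the final row. The result is the
#' `[P_N, P_A, P_Hb, minimal_energy]` matrix the second stage consumes.
#'
#' @param timeline Smoothed stage-1 [prob_timeline()].
#' @param min_energy 2 Hz minimal-energy vector for the same record.
#' @return Numeric matrix with one row per 2 Hz grid point and columns
#'   `P_N`, `P_A`, `P_Hb`, `min_energy`.
#' @export
stage2_inputs <- function(timeline, min_energy) {
  tg <- length(min_energy)
  p <- timeline$probs
  if (nrow(p) > tg) p <- p[seq_len(tg), , drop = FALSE]
  if (nrow(p) < tg)
    p <- rbind(p, p[rep(nrow(p), tg - nrow(p)), , drop = FALSE])
  out <- cbind(p, min_energy)
  colnames(out) <- c("P_N", "P_A", "P_Hb", "min_energy")
  out
}

#' Build the stage-2 labelled window set
#'
#' Windows of 32 s (64 grid steps at 2 Hz) with 0.5 s stride over the four
#' input series. Each window's label is the class at its ending point
#' (half-open interval lookup: a point exactly at an episode end is
#' normal): `A` inside an apnea, `H` inside a hypopnea, `N` otherwise.
#'
#' @param inputs `T x 4` matrix from [stage2_inputs()]; all four series
#'   must share the grid (a length mismatch between the probability series
#'   and the energy series is an error there).
#' @param annotations Episode data.frame.
#' @param window_s Window length, seconds.
#' @return A [window_set()] with classes `N`, `A`, `H` and `time_s` equal
#'   to window end times.
#' @export
make_windows_stage2 <- function(inputs, annotations, window_s = 32) {
  steps <- round(window_s * 2)
  tg <- nrow(inputs)
  if (ncol(inputs) != 4) stop("stage-2 inputs must have 4 series")
  if (tg < steps)
    return(window_set(array(0, c(0, 4, steps)), character(0), numeric(0),
                      STAGE2_CLASSES))
  starts <- seq_len(tg - steps + 1L)
  end_s <- (starts + steps - 1L) * 0.5
  x <- extract_stage2_data(inputs, starts, steps)
  lab <- rep("N", length(starts))
  lab[point_in_intervals(end_s,
                         annotations[annotations$class == "apnea", ,
                                     drop = FALSE])] <- "A"
  lab[point_in_intervals(end_s,
                         annotations[annotations$class == "hypopnea", ,
                                     drop = FALSE])] <- "H"
  window_set(x, lab, end_s, STAGE2_CLASSES)
}

extract_stage2_data <- function(inputs, starts, steps) {
  tg <- nrow(inputs)
  idx <- outer(0:(steps - 1L), starts, `+`)
  x <- array(0, c(length(starts), 4, steps))
  for (d in 1:4)
    x[, d, ] <- t(matrix(inputs[, d][idx], nrow = steps))
  x
}

#' Train the stage-2 network
#'
#' Same topology as stage 1 (the default full-scale training runs 100
#' epochs), over classes `N`, `A`, `H`.
#'
#' @param ws Balanced stage-2 [window_set()].
#' @param config A [net_config()].
#' @return An `sdb_lstm` model.
#' @export
train_stage2 <- function(ws, config = net_config(epochs = 100)) {
  train_lstm(ws$x, ws$labels, config, classes = STAGE2_CLASSES)
}

#' Predict the stage-2 probability timeline
#'
#' Probabilities are timestamped at the window END: stage-2 labels are
#' defined by the window ending point, so episode boundaries read off the
#' argmax series need no offset correction.
#'
#' @param inputs `T x 4` matrix from [stage2_inputs()].
#' @param model Stage-2 `sdb_lstm`.
#' @param window_s Window length, seconds.
#' @return A [prob_timeline()] over `N`, `A`, `H`, starting at
#'   `t = window_s`.
#' @export
predict_timeline_stage2 <- function(inputs, model, window_s = 32) {
  steps <- round(window_s * 2)
  tg <- nrow(inputs)
  if (tg < steps) stop("record shorter than one stage-2 window")
  starts <- seq_len(tg - steps + 1L)
  x <- extract_stage2_data(inputs, starts, steps)
  prob_timeline((starts + steps - 1L) * 0.5, predict(model, x),
                model$classes)
}
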