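# Postprocessing: the stage-2 N/A/H probability timeline is turned into
# discrete apnea/hypopnea episodes. Episode borders are placed where the
# maximum-probability label changes between N and {A, H}; switches between
# A and H do not split an episode. Each episode gets the class held by the
# majority of its grid points and a certainty score (mean probability of
# the assigned class), which is then thresholded per class. Thresholding
# whole episodes by mean score (rather than singling out grid points)
# keeps episodes from fragmenting as the threshold rises.

#' Extract candidate episodes from the stage-2 timeline
#'
#' Maximal runs of grid points whose argmax class is `A` or `H` form
#' candidate episodes (`[first point, last point + 0.5)` in seconds). The
#' assigned class is the one holding the argmax at the majority of the
#' episode's points; ties are broken by the higher mean class probability,
#' then in favour of apnea. Certainty is the arithmetic mean of the
#' assigned class's probability over all the episode's grid points, and
#' the mean normal-breathing probability is recorded for the additional
#' marking step.
#'
#' @param timeline A [prob_timeline()] over `N`, `A`, `H`.
#' @return A data.frame with columns `start_s`, `end_s`, `class`
#'   (`apnea`/`hypopnea`), `certainty` and `mean_N_prob`; empty for an
#'   all-normal timeline.
#' @export
extract_episodes <- function(timeline) {
  stopifnot(identical(timeline$classes, STAGE2_CLASSES))
  p <- timeline$probs
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      class = character(0), certainty = numeric(0),
                      mean_N_prob = numeric(0))
  if (!nrow(p)) return(empty)
  am <- max.col(p, ties.method = "first")        # 1 = N, 2 = A, 3 = H
  ev <- am != 1L
  if (!any(ev)) return(empty)
  r <- rle(ev)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- empty
  for (k in which(r$values)) {
    i <- starts[k]:ends[k]
    n_a <- sum(am[i] == 2L); n_h <- sum(am[i] == 3L)
    cls <- if (n_a > n_h) "apnea"
    else if (n_h > n_a) "hypopnea"
    else {
      ma <- mean(p[i, "A"]); mh <- mean(p[i, "H"])
      if (mh > ma) "hypopnea" else "apnea"
    }
    col <- if (cls == "apnea") "A" else "H"
    out <- rbind(out, data.frame(
      start_s = timeline$time_s[i[1]],
      end_s = timeline$time_s[i[length(i)]] + 0.5,
      class = cls,
      certainty = mean(p[i, col]),
      mean_N_prob = mean(p[i, "N"])))
  }
  out
}

#' Drop episodes shorter than the clinical minimum
#'
#' Events shorter than 10 s are not clinically scoreable; they are
#' excluded both from threshold determination and from final AI/HI
#' calculation.
#'
#' @param episodes Episode data.frame.
#' @param min_s Minimum duration in seconds (inclusive: exactly `min_s`
#'   is kept).
#' @return Filtered data.frame.
#' @export
filter_min_duration <- function(episodes, min_s = 10) {
  episodes[episodes$end_s - episodes$start_s >= min_s, , drop = FALSE]
}

#' Certainty thresholds for episode filtering
#'
#' @param A_thr,H_thr Apnea and hypopnea certainty thresholds in `[0, 1]`.
#' @return List of class `threshold_set`; `N_thr` is derived as
#'   `1 - max(A_thr, H_thr)` and is the bound under which an episode's
#'   mean normal-breathing probability triggers additional marking.
#' @export
threshold_set <- function(A_thr, H_thr) {
  stopifnot(A_thr >= 0, A_thr <= 1, H_thr >= 0, H_thr <= 1)
  structure(list(A_thr = A_thr, H_thr = H_thr,
                 N_thr = 1 - max(A_thr, H_thr)),
            class = "threshold_set")
}

# Count surviving episodes of one class per hour for a given certainty
# threshold; optionally including episodes reinstated by the N rule.
index_at_threshold <- function(episodes, cls, thr, trt_h,
                               n_thr = NULL) {
  ep <- filter_min_duration(episodes[episodes$class == cls, , drop = FALSE])
  keep <- ep$certainty >= thr
  if (!is.null(n_thr)) keep <- keep | ep$mean_N_prob < n_thr
  sum(keep) / trt_h
}

#' Optimize certainty thresholds on validation records
#'
#' Exhaustive grid search: the apnea threshold minimizes the RMSE between
#' predicted and true apnea indices (AI) across the validation records,
#' and the hypopnea threshold does the same for HI. Only episodes lasting
#' at least 10 s participate. Grid ties are broken toward the smallest
#' threshold (keeping more events). When `additional_marking` is on, a
#' second pass re-runs both searches with the N-rule reinstatement (using
#' the first-pass `N_thr`) active, since the extra events push the optimal
#' class thresholds upward.
#'
#' @param pred_episodes List of per-record predicted episode data.frames
#'   (with `certainty` and `mean_N_prob`).
#' @param true_annotations List of per-record true episode data.frames.
#' @param trt_h Numeric vector of total recording times, hours.
#' @param grid Candidate thresholds.
#' @param additional_marking Re-optimize with low-N reinstatement enabled.
#' @return A [threshold_set()].
#' @export
optimize_thresholds <- function(pred_episodes, true_annotations, trt_h,
                                grid = seq(0, 1, by = 0.02),
                                additional_marking = TRUE) {
  if (!length(grid)) stop("empty threshold grid")
  stopifnot(length(pred_episodes) == length(true_annotations),
            length(pred_episodes) == length(trt_h), length(pred_episodes) >= 1)
  true_index <- function(cls) vapply(seq_along(true_annotations), function(i) {
    ann <- true_annotations[[i]]
    nrow(filter_min_duration(ann[ann$class == cls, , drop = FALSE])) /
      trt_h[i]
  }, 0)
  best_thr <- function(cls, n_thr = NULL) {
    truth <- true_index(cls)
    rmse <- vapply(grid, function(th) {
      pred <- vapply(seq_along(pred_episodes), function(i)
        index_at_threshold(pred_episodes[[i]], cls, th, trt_h[i], n_thr), 0)
      sqrt(mean((pred - truth)^2))
    }, 0)
    grid[which.min(rmse)]                       # first minimum = smallest
  }
  a <- best_thr("apnea")
  h <- best_thr("hypopnea")
  if (additional_marking) {
    n_thr <- 1 - max(a, h)
    a <- best_thr("apnea", n_thr)
    h <- best_thr("hypopnea", n_thr)
  }
  threshold_set(a, h)
}

#' Apply certainty thresholds (with additional low-N marking)
#'
#' Keeps episodes whose certainty reaches their class threshold. Among the
#' episodes removed by that filter, any whose mean normal-breathing
#' probability is below `N_thr` is reinstated with its majority class:
#' these are the ambiguous events where apnea and hypopnea probabilities
#' are similar but normal probability is clearly low, i.e. the model is
#' sure something happened without being sure what. Reinstated episodes do
#' not bypass the 10 s duration filter applied downstream.
#'
#' @param episodes Episode data.frame from [extract_episodes()].
#' @param thresholds A [threshold_set()].
#' @param additional_marking Enable the low-N reinstatement.
#' @return Surviving episodes sorted by start, with a logical `reinstated`
#'   column.
#' @export
apply_thresholds <- function(episodes, thresholds,
                             additional_marking = TRUE) {
  if (!nrow(episodes)) {
    episodes$reinstated <- logical(0)
    return(episodes)
  }
  thr <- ifelse(episodes$class == "apnea", thresholds$A_thr,
                thresholds$H_thr)
  keep <- episodes$certainty >= thr
  reinstated <- !keep & additional_marking &
    episodes$mean_N_prob < thresholds$N_thr
  out <- episodes[keep | reinstated, , drop = FALSE]
  out$reinstated <- reinstated[keep | reinstated]
  out[order(out$start_s), , drop = FALSE]
}
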