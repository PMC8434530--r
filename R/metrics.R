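# Evaluation: event-per-hour indices (AI/HI/REI) with severity classes,
# 0.5 s epoch-based confusion matrices, index error statistics, and
# wake-period exclusion.

#' Apnea, hypopnea and respiratory event indices
#'
#' `AI` and `HI` are the apnea and hypopnea counts per hour; `REI` is
#' their sum. Total recording time (TRT) is used as the denominator, the
#' standard surrogate when no sleep staging is available (REI in place of
#' AHI).
#'
#' @param episodes Episode data.frame, already filtered to >= 10 s events.
#' @param trt_h Total recording time in hours (> 0).
#' @return List of class `index_set` with `AI`, `HI`, `REI`, `TRT_h`.
#' @export
compute_indices <- function(episodes, trt_h) {
  if (trt_h <= 0) stop("TRT must be positive")
  ai <- sum(episodes$class == "apnea") / trt_h
  hi <- sum(episodes$class == "hypopnea") / trt_h
  structure(list(AI = ai, HI = hi, REI = ai + hi, TRT_h = trt_h),
            class = "index_set")
}

#' Sleep apnea severity class from REI
#'
#' Standard clinical boundaries: REI < 5 Normal, 5 <= REI < 15 Mild,
#' 15 <= REI < 30 Moderate, REI >= 30 Severe.
#'
#' @param rei Numeric REI value(s).
#' @return Factor with levels Normal, Mild, Moderate, Severe.
#' @export
severity_class <- function(rei) {
  cut(rei, breaks = c(-Inf, 5, 15, 30, Inf),
      labels = c("Normal", "Mild", "Moderate", "Severe"), right = FALSE)
}

#' Epoch-based confusion matrix at 0.5 s resolution
#'
#' Every 0.5 s grid point of the recording is labelled by half-open
#' point-in-interval lookup against the true and the predicted episode
#' sets, and the 3x3 confusion counts over normal (N), hypopnea (H) and
#' apnea (A) are accumulated. Per-class accuracy is the diagonal of the
#' row-normalized matrix; total accuracy is the fraction of correctly
#' classified grid points.
#'
#' @param pred_episodes Predicted episode data.frame.
#' @param true_annotations True episode data.frame.
#' @param duration_s Record duration, seconds.
#' @param exclude_intervals Optional data.frame of intervals (e.g. wake)
#'   whose grid points are dropped from the evaluation.
#' @return List of class `epoch_confusion`: integer `counts` (true class
#'   in rows), `normalized` (row-normalized), `per_class_accuracy` and
#'   `total_accuracy`.
#' @export
epoch_confusion <- function(pred_episodes, true_annotations, duration_s,
                            exclude_intervals = NULL) {
  tg <- seq(0, duration_s - 0.5, by = 0.5)
  if (!is.null(exclude_intervals) && nrow(exclude_intervals))
    tg <- tg[!point_in_intervals(tg, exclude_intervals)]
  lab <- function(ann) {
    l <- rep("N", length(tg))
    l[point_in_intervals(tg, ann[ann$class == "hypopnea", , drop = FALSE])] <- "H"
    l[point_in_intervals(tg, ann[ann$class == "apnea", , drop = FALSE])] <- "A"
    factor(l, levels = c("N", "H", "A"))
  }
  counts <- table(true = lab(true_annotations), pred = lab(pred_episodes))
  confusion_from_counts(unclass(counts))
}

confusion_from_counts <- function(counts) {
  norm <- counts / pmax(rowSums(counts), 1)
  structure(list(counts = counts, normalized = norm,
                 per_class_accuracy = diag(norm),
                 total_accuracy = sum(diag(counts)) / max(sum(counts), 1)),
            class = "epoch_confusion")
}

#' Aggregate epoch confusion matrices across records
#'
#' Raw counts are summed and then normalized, so records contribute in
#' proportion to their number of grid points.
#'
#' @param confusions List of [epoch_confusion()] results.
#' @return One aggregated `epoch_confusion`.
#' @export
combine_confusions <- function(confusions) {
  counts <- Reduce(`+`, lapply(confusions, `[[`, "counts"))
  confusion_from_counts(counts)
}

#' @export
print.epoch_confusion <- function(x, ...) {
  cat("<epoch_confusion> row-normalized (true class in rows):\n")
  print(round(x$normalized, 4))
  cat(sprintf("total accuracy: %.4f\n", x$total_accuracy))
  invisible(x)
}

#' Error statistics for index estimation
#'
#' Signed errors are predicted minus true. Reports mean absolute error,
#' the standard deviation and extremes of the signed errors, and Pearson
#' and Spearman correlations of the paired values (undefined, `NA`, with
#' fewer than two pairs).
#'
#' @param pred,true Numeric vectors of per-record index values.
#' @return List with `MAE`, `SD`, `min_err`, `max_err`, `pearson_r`,
#'   `spearman_r`, `n`.
#' @export
rei_error_stats <- function(pred, true) {
  stopifnot(length(pred) == length(true))
  err <- pred - true
  n <- length(err)
  can_cor <- n >= 2 && sd(pred) > 0 && sd(true) > 0
  list(MAE = mean(abs(err)),
       SD = if (n >= 2) sd(err) else NA_real_,
       min_err = min(err), max_err = max(err),
       pearson_r = if (can_cor) cor(pred, true) else NA_real_,
       spearman_r = if (can_cor) cor(pred, true, method = "spearman")
                    else NA_real_,
       n = n)
}

#' Remove episodes occurring during wake
#'
#' Databases often leave respiratory events unannotated during wake, so
#' evaluations can be rerun with wake-time episodes removed from both the
#' true and the predicted sets. By default an episode is considered "in
#' wake" when its midpoint lies inside a wake interval; `rule` can demand
#' any overlap or full containment instead.
#'
#' @param episodes Episode data.frame.
#' @param wake_intervals Data.frame with `start_s`, `end_s`.
#' @param rule Removal rule: `"midpoint"` (default), `"overlap"`, or
#'   `"inside"`.
#' @return Episodes outside wake.
#' @export
exclude_wake <- function(episodes, wake_intervals,
                         rule = c("midpoint", "overlap", "inside")) {
  rule <- match.arg(rule)
  if (!nrow(episodes) || is.null(wake_intervals) || !nrow(wake_intervals))
    return(episodes)
  drop <- switch(rule,
    midpoint = point_in_intervals((episodes$start_s + episodes$end_s) / 2,
                                  wake_intervals),
    overlap = vapply(seq_len(nrow(episodes)), function(i)
      any(wake_intervals$start_s < episodes$end_s[i] &
            wake_intervals$end_s > episodes$start_s[i]), NA),
    inside = vapply(seq_len(nrow(episodes)), function(i)
      any(wake_intervals$start_s <= episodes$start_s[i] &
            wake_intervals$end_s >= episodes$end_s[i]), NA))
  episodes[!drop, , drop = FALSE]
}
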