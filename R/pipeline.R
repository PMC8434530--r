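# End-to-end orchestration: preprocess -> stage 1 -> minimal energy ->
# stage 2 -> postprocess -> evaluation, with a 70/10/20 train/validation/
# test split (validation records are used only for threshold optimization,
# never for network training).

#' Preprocess one corpus entry
#'
#' @param entry A `sim_record` or a list with `record`, `annotations`,
#'   `wake`.
#' @param pp_config A [preprocess_config()].
#' @return List with the preprocessed `record`, `annotations`, `wake`,
#'   `trt_h` and the `quality` screen result.
#' @export
prepare_record <- function(entry, pp_config = preprocess_config()) {
  quality <- quality_pass(entry$record, pp_config$quality_energy_threshold)
  rec <- preprocess_record(entry$record, pp_config)
  list(record = rec, annotations = entry$annotations,
       wake = if (is.null(entry$wake))
         data.frame(start_s = numeric(0), end_s = numeric(0))
       else entry$wake,
       trt_h = rec$duration_s / 3600, quality = quality)
}

# Stage-1 timeline + stage-2 input matrix for one prepared record.
stage2_input_matrix <- function(prep, stage1_model) {
  tl1 <- smooth_timeline(predict_timeline_stage1(prep$record, stage1_model))
  stage2_inputs(tl1, minimal_energy_signal(prep$record))
}

#' Train the full two-stage detector
#'
#' Builds and balances the stage-1 window set over the training records,
#' trains the first network, constructs the stage-2 inputs (smoothed
#' stage-1 timelines + minimal-energy signal) for the training records,
#' trains the second network, and optimizes the certainty thresholds on
#' the validation records.
#'
#' @param train Prepared training records (list of [prepare_record()]
#'   results).
#' @param validation Prepared validation records for threshold
#'   optimization.
#' @param net1,net2 [net_config()] for the two stages.
#' @param pp_config The [preprocess_config()] used (stored for inference).
#' @param threshold_grid Candidate certainty thresholds.
#' @param additional_marking Enable low-N episode reinstatement.
#' @param max_per_class Per-class cap passed to [balance_classes()].
#' @param seed Seed for the balancing draws.
#' @return List of class `sdb_model` with `stage1`, `stage2`,
#'   `thresholds`, `pp_config` and `additional_marking`.
#' @export
train_sdb_model <- function(train, validation,
                            net1 = net_config(epochs = 50),
                            net2 = net_config(epochs = 100),
                            pp_config = preprocess_config(),
                            threshold_grid = seq(0, 1, by = 0.02),
                            additional_marking = TRUE,
                            max_per_class = Inf, seed = 1L) {
  ws1 <- bind_window_sets(lapply(train, function(p)
    make_windows_stage1(p$record, p$annotations)))
  ws1 <- balance_classes(ws1, seed = seed, max_per_class = max_per_class)
  stage1 <- train_stage1(ws1, net1)

  ws2 <- bind_window_sets(lapply(train, function(p)
    make_windows_stage2(stage2_input_matrix(p, stage1), p$annotations)))
  ws2 <- balance_classes(ws2, seed = seed + 1L,
                         max_per_class = max_per_class)
  stage2 <- train_stage2(ws2, net2)

  val_eps <- lapply(validation, function(p)
    extract_episodes(predict_timeline_stage2(
      stage2_input_matrix(p, stage1), stage2)))
  thresholds <- optimize_thresholds(
    val_eps, lapply(validation, `[[`, "annotations"),
    vapply(validation, `[[`, 0, "trt_h"),
    grid = threshold_grid, additional_marking = additional_marking)

  structure(list(stage1 = stage1, stage2 = stage2,
                 thresholds = thresholds, pp_config = pp_config,
                 additional_marking = additional_marking),
            class = "sdb_model")
}

#' @export
print.sdb_model <- function(x, ...) {
  cat("<sdb_model> two-stage LSTM detector\n")
  cat(sprintf("  thresholds: A %.2f, H %.2f (N %.2f), additional marking %s\n",
              x$thresholds$A_thr, x$thresholds$H_thr, x$thresholds$N_thr,
              if (x$additional_marking) "on" else "off"))
  invisible(x)
}

#' Detect episodes in one prepared record
#'
#' Full inference: stage-1 timeline, minimal-energy signal, stage-2
#' timeline, episode extraction, certainty thresholding (with additional
#' low-N marking when enabled). Episodes shorter than 10 s are retained in
#' the output labels; index computation filters them.
#'
#' @param model A trained `sdb_model`.
#' @param prep A [prepare_record()] result.
#' @param additional_marking Override the model's additional-marking
#'   setting (e.g. for ablation).
#' @return List with `episodes` (final thresholded set), `raw_episodes`
#'   (before thresholding) and `timeline` (stage-2 probabilities).
#' @export
detect_episodes <- function(model, prep,
                            additional_marking = model$additional_marking) {
  tl2 <- predict_timeline_stage2(stage2_input_matrix(prep, model$stage1),
                                 model$stage2)
  raw <- extract_episodes(tl2)
  list(episodes = apply_thresholds(raw, model$thresholds,
                                   additional_marking),
       raw_episodes = raw, timeline = tl2)
}

#' Evaluate detections against ground truth
#'
#' Per record: the 0.5 s epoch confusion matrix and predicted/true
#' AI/HI/REI (>= 10 s episodes only). Aggregates confusion counts across
#' records and computes index error statistics and severity classes. With
#' `wake_exclusion`, episodes during wake are removed from both the
#' predicted and the true sets and wake grid points are dropped from the
#' epoch evaluation.
#'
#' @param detections List of [detect_episodes()] results.
#' @param prepared Matching list of prepared records.
#' @param wake_exclusion Remove wake-time episodes/points.
#' @return List of class `sdb_evaluation`: `confusion` (aggregate),
#'   `per_record` (data.frame of indices), `rei_stats`, `ai_stats`,
#'   `hi_stats`, `severity_table`.
#' @export
evaluate_sdb <- function(detections, prepared, wake_exclusion = FALSE) {
  stopifnot(length(detections) == length(prepared))
  confs <- list()
  idx <- data.frame()
  for (i in seq_along(detections)) {
    prep <- prepared[[i]]
    pred <- detections[[i]]$episodes
    truth <- prep$annotations
    excl <- NULL
    if (wake_exclusion && nrow(prep$wake)) {
      pred <- exclude_wake(pred, prep$wake)
      truth <- exclude_wake(truth, prep$wake)
      excl <- prep$wake
    }
    confs[[i]] <- epoch_confusion(pred, truth, prep$record$duration_s,
                                  exclude_intervals = excl)
    pi_ <- compute_indices(filter_min_duration(pred), prep$trt_h)
    ti <- compute_indices(filter_min_duration(truth), prep$trt_h)
    idx <- rbind(idx, data.frame(
      record = i, AI_pred = pi_$AI, HI_pred = pi_$HI, REI_pred = pi_$REI,
      AI_true = ti$AI, HI_true = ti$HI, REI_true = ti$REI))
  }
  sev <- table(true = severity_class(idx$REI_true),
               pred = severity_class(idx$REI_pred))
  structure(list(confusion = combine_confusions(confs),
                 per_record = idx,
                 rei_stats = rei_error_stats(idx$REI_pred, idx$REI_true),
                 ai_stats = rei_error_stats(idx$AI_pred, idx$AI_true),
                 hi_stats = rei_error_stats(idx$HI_pred, idx$HI_true),
                 severity_table = sev),
            class = "sdb_evaluation")
}

#' @export
print.sdb_evaluation <- function(x, ...) {
  print(x$confusion)
  cat(sprintf("REI MAE: %.3f (r = %.3f), AI MAE: %.3f, HI MAE: %.3f\n",
              x$rei_stats$MAE, x$rei_stats$pearson_r, x$ai_stats$MAE,
              x$hi_stats$MAE))
  invisible(x)
}

#' Split a corpus into train/validation/test
#'
#' Proportions default to 70/10/20. The split is by record position after
#' a seeded shuffle, so a fixed seed reproduces it.
#'
#' @param n Number of records.
#' @param split Named proportions (`train`, `val`, `test`).
#' @param seed Shuffle seed.
#' @return List of integer index vectors `train`, `val`, `test`.
#' @export
split_corpus <- function(n, split = c(train = 0.7, val = 0.1, test = 0.2),
                         seed = 1L) {
  stopifnot(abs(sum(split) - 1) < 1e-8, n >= 3)
  ord <- with_seed(seed, sample(n))
  n_train <- min(max(1L, round(split[["train"]] * n)), n - 2L)
  n_val <- min(max(1L, round(split[["val"]] * n)), n - n_train - 1L)
  list(train = sort(ord[seq_len(n_train)]),
       val = sort(ord[n_train + seq_len(n_val)]),
       test = sort(ord[(n_train + n_val + 1L):n]))
}

#' Run a full simulate/train/evaluate experiment
#'
#' Convenience driver: screens record quality, splits the corpus, trains
#' both stages and the thresholds, detects episodes on the held-out test
#' records and evaluates them (optionally also with wake exclusion).
#'
#' @param corpus List of records (each with `record`, `annotations`,
#'   `wake`), e.g. from [generate_corpus()].
#' @param split Train/validation/test proportions.
#' @param pp_config,net1,net2,threshold_grid,additional_marking,max_per_class
#'   Passed through to the training steps.
#' @param seed Seed for the split and balancing.
#' @return List of class `sdb_experiment`: the `model`, index vectors
#'   `split`, prepared `test` records, their `detections`, `evaluation`
#'   and `evaluation_wake_excluded` (`NULL` when no record has wake data).
#' @export
run_sdb_experiment <- function(corpus,
                               split = c(train = 0.7, val = 0.1,
                                         test = 0.2),
                               pp_config = preprocess_config(),
                               net1 = net_config(epochs = 50),
                               net2 = net_config(epochs = 100),
                               threshold_grid = seq(0, 1, by = 0.02),
                               additional_marking = TRUE,
                               max_per_class = Inf, seed = 1L) {
  prepared <- lapply(corpus, prepare_record, pp_config = pp_config)
  ok <- vapply(prepared, function(p) p$quality$pass, NA)
  if (any(!ok)) {
    warning(sum(!ok), " record(s) failed the energy quality screen and ",
            "were excluded")
    prepared <- prepared[ok]
  }
  idx <- split_corpus(length(prepared), split, seed)
  model <- train_sdb_model(prepared[idx$train], prepared[idx$val],
                           net1 = net1, net2 = net2, pp_config = pp_config,
                           threshold_grid = threshold_grid,
                           additional_marking = additional_marking,
                           max_per_class = max_per_class, seed = seed)
  test <- prepared[idx$test]
  detections <- lapply(test, function(p) detect_episodes(model, p))
  has_wake <- any(vapply(test, function(p) nrow(p$wake) > 0, NA))
  structure(list(model = model, split = idx, test = test,
                 detections = detections,
                 evaluation = evaluate_sdb(detections, test),
                 evaluation_wake_excluded = if (has_wake)
                   evaluate_sdb(detections, test, wake_exclusion = TRUE)
                 else NULL),
            class = "sdb_experiment")
}
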