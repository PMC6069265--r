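#' Walking-speed band of a trial
#'
#' Low speed is `v <= m - s`, high is `v > m + s`, everything between is
#' normal, where `m` and `s` are the mean and standard deviation of the
#' population walking-speed proxy.
#'
#' @param trial_speed Speed proxy of the trial (mean step-velocity
#'   magnitude).
#' @param population_mean,population_sd Population statistics (`sd > 0`).
#' @return `"low"`, `"normal"` or `"high"` (vectorised over `trial_speed`).
#' @export
speed_class <- function(trial_speed, population_mean, population_sd) {
  if (population_sd <= 0) stop("population_sd must be positive")
  ifelse(trial_speed <= population_mean - population_sd, "low",
         ifelse(trial_speed > population_mean + population_sd, "high",
                "normal"))
}

#' Step-detection accuracy
#'
#' `100 * (1 - |detected - true| / true)`: symmetric in over- and
#' under-counting.
#'
#' @param detected,true Step counts (`true > 0`; vectorised).
#' @return Percentage (can fall below 0 for gross errors).
#' @export
step_accuracy <- function(detected, true) {
  if (any(true <= 0)) stop("true step count must be positive")
  100 * (1 - abs(detected - true) / true)
}

#' Distance-estimation metrics per activity and speed band
#'
#' For each activity x speed cell: accuracy = mean of the per-trial
#' `100 * (1 - |D_est - D_true| / D_true)`, Std = standard deviation of the
#' estimated distances (m). Per activity: NMSE =
#' `100 * sum((D_est - D_true)^2) / sum(D_true^2)`.
#'
#' @param results `data.frame` with columns `activity`, `speed_class`,
#'   `distance_est`, `distance_true`.
#' @return List with `by_cell` (`data.frame`: activity, speed_class, n,
#'   accuracy, std_m) and `by_activity` (`data.frame`: activity, n,
#'   accuracy, nmse).
#' @export
distance_metrics <- function(results) {
  need <- c("activity", "speed_class", "distance_est", "distance_true")
  stopifnot(all(need %in% names(results)))
  acc <- 100 * (1 - abs(results$distance_est - results$distance_true) /
                  results$distance_true)
  cells <- unique(results[, c("activity", "speed_class")])
  by_cell <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- results$activity == cells$activity[i] &
      results$speed_class == cells$speed_class[i]
    if (sum(sel) < 2L)
      warning("cell ", cells$activity[i], "/", cells$speed_class[i],
              " has fewer than 2 trials; Std is NA")
    data.frame(activity = cells$activity[i],
               speed_class = cells$speed_class[i], n = sum(sel),
               accuracy = mean(acc[sel]),
               std_m = if (sum(sel) >= 2L)
                 stats::sd(results$distance_est[sel]) else NA_real_)
  }))
  by_activity <- do.call(rbind, lapply(unique(results$activity), function(a) {
    sel <- results$activity == a
    data.frame(activity = a, n = sum(sel), accuracy = mean(acc[sel]),
               nmse = 100 * sum((results$distance_est[sel] -
                                   results$distance_true[sel])^2) /
                 sum(results$distance_true[sel]^2))
  }))
  list(by_cell = by_cell, by_activity = by_activity)
}

#' Run the full pipeline on one trial
#'
#' Classification (optional, when trained stages are given), step detection
#' under the claimed label, misclassification feedback with at most one
#' reroute (a second conflicting feedback would only ping-pong; the second
#' detector's result stands), estimator selection and distance estimation.
#'
#' @param series Raw or preprocessed `accel_series`.
#' @param stage1,stage2 Trained `activity_stage` objects, or `NULL` to use
#'   `activity` as given.
#' @param kmodels Nested list of fitted `klocpoly` models indexed as
#'   `kmodels[[activity]]` (fitted with the activity's selected method), or
#'   `NULL` to skip distance estimation.
#' @param height Subject height in metres.
#' @param activity True/claimed label (used when `stage1` is `NULL`).
#' @param control A [wg_control()] list.
#' @return List with `activity` (final label), `initial_activity`,
#'   `feedback` (feedback events seen), `detection`, `distance` (`NA` when
#'   not estimated), `trial_speed` (mean step velocity).
#' @export
run_trial <- function(series, stage1 = NULL, stage2 = NULL, kmodels = NULL,
                      height = 1.7, activity = NULL,
                      control = wg_control()) {
  pre <- if (is.null(series$rate) || series$rate != control$resample_rate)
    preprocess_series(series, control) else series
  if (!is.null(stage1)) {
    fm <- trial_features(pre, control)
    label <- classify_trial(stage1, stage2, fm)
  } else {
    if (is.null(activity)) stop("either trained stages or an activity label is required")
    label <- .check_activity(activity)
    fm <- NULL
  }
  initial <- label
  det <- detect_steps(pre, label, control)
  fb <- character(0)
  if (det$feedback != "none") {
    fb <- det$feedback
    label <- if (det$feedback == "to_swing_detector") "swinging"
    else if (!is.null(stage2) && !is.null(fm)) .majority(predict_windows(stage2, fm))
    else stop("feedback to stage 2 requires a trained stage-2 classifier")
    det <- detect_steps(pre, label, control)
    ## at most one reroute: on a second, conflicting feedback the second
    ## detector's result stands (prevents ping-pong)
    if (det$feedback != "none") {
      warning("conflicting feedback after reroute; keeping second result")
      fb <- c(fb, det$feedback)
      det <- detect_steps(pre, label, control, feedback = FALSE)
    }
  }
  v <- if (length(det$steps))
    vapply(det$steps, step_velocity, numeric(1)) else numeric(0)
  distance <- NA_real_
  if (!is.null(kmodels) && length(det$steps)) {
    km <- kmodels[[label]]
    if (!is.null(km))
      distance <- estimate_distance(det, km, height)$distance
  }
  list(activity = label, initial_activity = initial, feedback = fb,
       detection = det, distance = distance,
       trial_speed = if (length(v)) mean(v) else NA_real_)
}

## Fit per-activity K models (each with its selected estimator) from
## training trials: detection under the true label, training K pairs from
## the known 20 m totals.
.fit_kmodels <- function(detections, meta, control,
                         methods = NULL) {
  out <- list()
  for (a in unique(meta$activity)) {
    method <- if (is.null(methods)) select_estimator(a, control) else
      methods[[a]]
    idx <- which(meta$activity == a)
    pairs <- do.call(rbind, lapply(idx, function(i) {
      if (!length(detections[[i]]$steps)) return(NULL)
      compute_training_k(detections[[i]], meta$true_distance_m[i], method,
                         meta$height_m[i])
    }))
    if (is.null(pairs) || nrow(pairs) < control$degree + 1L) next
    out[[a]] <- fit_k_model(pairs$v_bar, pairs$k, method,
                            degree = control$degree,
                            bandwidth = control$bandwidth)
  }
  out
}

#' Leave-one-sample-out evaluation of the full pipeline
#'
#' For every trial in turn: both classifier stages and all per-activity
#' K-factor models are trained on the remaining trials, then the held-out
#' trial runs the complete pipeline (classification, detection with
#' feedback, per-activity estimator). Results are aggregated into stage
#' confusion matrices, per-activity step accuracy and per-activity x
#' speed-band distance metrics. Deterministic given the dataset.
#'
#' @param dataset A `wg_dataset` from [generate_dataset()] (>= 2 trials).
#' @param control A [wg_control()] list.
#' @param progress Print a dot per fold.
#' @return An object of class `loso_report`: list with `results` (per-trial
#'   `data.frame`), `stage1_confusion`, `stage2_confusion`, `step_accuracy`
#'   (per activity: mean, sd), `distance` (see [distance_metrics()]),
#'   `estimators` (activity -> method map used).
#' @export
loso_evaluate <- function(dataset, control = wg_control(), progress = FALSE) {
  stopifnot(inherits(dataset, "wg_dataset"))
  meta <- dataset$meta
  n <- nrow(meta)
  if (n < 2L) stop("LOSO needs at least 2 trials")
  pre <- lapply(dataset$trials,
                function(tr) preprocess_series(tr$series, control))
  feats <- lapply(pre, trial_features, control = control)
  dets <- lapply(seq_len(n), function(i)
    detect_steps(pre[[i]], meta$activity[i], control))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (progress) cat(".")
    tr_idx <- setdiff(seq_len(n), i)
    fm <- do.call(rbind, feats[tr_idx])
    lab <- rep(meta$activity[tr_idx],
               vapply(feats[tr_idx], nrow, integer(1)))
    s1 <- train_stage(1L, fm, lab)
    ns <- lab != "swinging"
    s2 <- train_stage(2L, fm[ns, , drop = FALSE], lab[ns])
    km <- .fit_kmodels(dets[tr_idx], meta[tr_idx, ], control)
    res <- run_trial(pre[[i]], s1, s2, km, height = meta$height_m[i],
                     control = control)
    rows[[i]] <- data.frame(
      trial_id = meta$trial_id[i], subject = meta$subject[i],
      activity = meta$activity[i], predicted = res$activity,
      initial_predicted = res$initial_activity,
      feedback = paste(res$feedback, collapse = "+"),
      steps_detected = length(res$detection$steps),
      steps_true = meta$n_steps[i],
      distance_est = res$distance, distance_true = meta$true_distance_m[i],
      trial_speed = res$trial_speed)
  }
  if (progress) cat("\n")
  results <- do.call(rbind, rows)
  ## speed bands within activity: the velocity proxy scales with the
  ## activity's signal amplitude, so only within-activity comparisons are
  ## meaningful
  results$speed_class <- NA_character_
  for (a in unique(results$activity)) {
    sel <- results$activity == a & !is.na(results$trial_speed)
    if (sum(sel) >= 2L)
      results$speed_class[sel] <- speed_class(results$trial_speed[sel],
                                              mean(results$trial_speed[sel]),
                                              stats::sd(results$trial_speed[sel]))
  }
  truth1 <- ifelse(results$activity == "swinging", "swinging", "other")
  pred1 <- ifelse(results$initial_predicted == "swinging", "swinging",
                  "other")
  ## the feedback loop corrects stage-1 errors before the final label
  pred1_final <- ifelse(results$predicted == "swinging", "swinging", "other")
  stage1_conf <- table(truth = truth1, predicted = pred1_final)
  ns <- results$activity != "swinging" & results$predicted != "swinging"
  stage2_conf <- table(truth = factor(results$activity[ns],
                                      levels = setdiff(wg_activities,
                                                       "swinging")),
                       predicted = factor(results$predicted[ns],
                                          levels = setdiff(wg_activities,
                                                           "swinging")))
  sa <- step_accuracy(results$steps_detected, results$steps_true)
  step_acc <- do.call(rbind, lapply(unique(results$activity), function(a) {
    sel <- results$activity == a
    data.frame(activity = a, mean_accuracy = mean(sa[sel]),
               sd_accuracy = stats::sd(sa[sel]))
  }))
  dm <- distance_metrics(results[!is.na(results$distance_est), ])
  structure(list(results = results, stage1_confusion = stage1_conf,
                 stage2_confusion = stage2_conf, step_accuracy = step_acc,
                 distance = dm,
                 estimators = control$estimator_map,
                 initial_stage1_confusion = table(truth = truth1,
                                                  predicted = pred1)),
            class = "loso_report")
}

#' @export
print.loso_report <- function(x, ...) {
  r <- x$results
  cat(sprintf("<loso_report> %d trials\n", nrow(r)))
  cat(sprintf("  trial classification accuracy: %.1f%%\n",
              100 * mean(r$predicted == r$activity)))
  cat(sprintf("  mean step accuracy: %.1f%%\n",
              mean(step_accuracy(r$steps_detected, r$steps_true))))
  ok <- !is.na(r$distance_est)
  if (any(ok)) {
    err <- abs(r$distance_est[ok] - r$distance_true[ok]) / r$distance_true[ok]
    cat(sprintf("  mean distance error: %.2f%% over %d trials\n",
                100 * mean(err), sum(ok)))
  }
  cat("  estimators:", paste(names(x$estimators), x$estimators, sep = "=",
                             collapse = ", "), "\n")
  invisible(x)
}
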