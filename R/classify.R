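## Feature subsets per classifier stage. Stage 1 (swing vs the rest) uses
## intensity/spectral features; stage 2 (the four centre-of-mass activities)
## adds the orientation-sensitive moments instead of SMA/IM.
.stage_features <- function(stage_id) {
  if (stage_id == 1L)
    c("SMA", "IM_x", "IM_y", "IM_z", "AE",
      grep("^bp_", wg_feature_names, value = TRUE),
      grep("^pp_", wg_feature_names, value = TRUE))
  else
    c("mu_x", "mu_y", "mu_z", "sigma_x", "sigma_y", "sigma_z", "AE",
      grep("^bp_", wg_feature_names, value = TRUE),
      grep("^pp_", wg_feature_names, value = TRUE))
}

#' Train one stage of the activity classifier
#'
#' Stage 1 is a binary radial-kernel SVM separating arm swinging from the
#' four centre-of-mass activities (labels are collapsed to
#' `swinging`/`other` internally); stage 2 is a 4-class SVM among texting,
#' calling, pocket and suitcase and must not see swinging rows. Features are
#' z-standardised with training-set statistics stored in the stage.
#'
#' @param stage_id 1 or 2.
#' @param features Numeric matrix of window features with (at least) the 23
#'   named columns of [wg_feature_names].
#' @param labels Character vector of activity labels, one per row.
#' @param cost SVM regularisation parameter (default 1).
#' @return An object of class `activity_stage`.
#' @export
train_stage <- function(stage_id, features, labels, cost = 1) {
  stage_id <- as.integer(stage_id)
  stopifnot(stage_id %in% c(1L, 2L), nrow(features) == length(labels))
  bad <- setdiff(unique(labels), wg_activities)
  if (length(bad)) stop("unknown activity label(s): ", paste(bad, collapse = ", "))
  if (stage_id == 1L) {
    y <- ifelse(labels == "swinging", "swinging", "other")
  } else {
    if (any(labels == "swinging"))
      stop("stage 2 must not be trained on swinging rows")
    y <- labels
  }
  if (length(unique(y)) < 2L)
    stop("training data contains a single class")
  cols <- .stage_features(stage_id)
  miss <- setdiff(cols, colnames(features))
  if (length(miss)) stop("missing feature column(s): ", paste(miss, collapse = ", "))
  x <- features[, cols, drop = FALSE]
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  model <- e1071::svm(xs, factor(y), kernel = "radial", cost = cost,
                      scale = FALSE)
  structure(list(stage_id = stage_id, features = cols, center = center,
                 scale = scale, model = model, classes = sort(unique(y))),
            class = "activity_stage")
}

#' @export
print.activity_stage <- function(x, ...) {
  cat(sprintf("<activity_stage %d> classes: %s; %d features, %d SVs\n",
              x$stage_id, paste(x$classes, collapse = "/"),
              length(x$features), x$model$tot.nSV))
  invisible(x)
}

#' Predict per-window activity labels
#'
#' @param stage An `activity_stage` from [train_stage()].
#' @param features Feature matrix carrying the stage's feature columns.
#' @return Character vector of labels, one per row (stage 1: `swinging` or
#'   `other`).
#' @export
predict_windows <- function(stage, features) {
  stopifnot(inherits(stage, "activity_stage"))
  if (nrow(features) == 0L) return(character(0))
  miss <- setdiff(stage$features, colnames(features))
  if (length(miss)) stop("missing feature column(s): ", paste(miss, collapse = ", "))
  x <- features[, stage$features, drop = FALSE]
  xs <- sweep(sweep(x, 2L, stage$center), 2L, stage$scale, "/")
  as.character(stats::predict(stage$model, xs))
}

## Majority vote with a deterministic tie rule: prefer the label given in
## `tie_pref`, then lexicographic order.
.majority <- function(votes, tie_pref = NULL) {
  tab <- table(votes)
  winners <- names(tab)[tab == max(tab)]
  if (!is.null(tie_pref) && tie_pref %in% winners) return(tie_pref)
  sort(winners)[1L]
}

#' Classify one trial from its windows
#'
#' Hierarchical decision: the stage-1 majority vote over all windows decides
#' swinging versus the centre-of-mass group (ties go to the group, the
#' larger prior: 4 of the 5 activities); if the group wins, the stage-2
#' majority vote over the same windows picks one of the four activities
#' (ties broken in lexicographic label order).
#'
#' @param stage1,stage2 Trained `activity_stage` objects.
#' @param features Feature matrix of the trial's windows (>= 1 row).
#' @return One of the five activity labels.
#' @export
classify_trial <- function(stage1, stage2, features) {
  if (nrow(features) < 1L) stop("at least one window required")
  v1 <- predict_windows(stage1, features)
  if (.majority(v1, tie_pref = "other") == "swinging") return("swinging")
  .majority(predict_windows(stage2, features))
}
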