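## Indices of strict local maxima / minima (first sample of a plateau).
.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  # left-strict / right-non-strict: exactly one index per flat-topped plateau
  i[x[i] > x[i - 1L] & x[i] >= x[i + 1L]]
}
.local_minima <- function(x) .local_maxima(-x)

## Greedy minimum-separation pruning: while two kept extrema are closer than
## min_sep samples, drop the less extreme of the offending pair.
.enforce_separation <- function(idx, value, min_sep) {
  while (length(idx) > 1L) {
    gaps <- diff(idx)
    j <- which(gaps < min_sep)[1L]
    if (is.na(j)) break
    drop <- if (value[j] >= value[j + 1L]) j + 1L else j
    idx <- idx[-drop]; value <- value[-drop]
  }
  idx
}

#' Build the single-axis detection signal
#'
#' Picks the detection axis -- by default the axis with the largest
#' periodogram power in the 1-3 Hz gait band, since the axis that carries
#' the vertical movement differs between wrist activities -- removes its
#' baseline and low-pass filters it again at 5 Hz to clean the extremum
#' structure.
#'
#' @param series A uniform, preprocessed `accel_series`.
#' @param activity Claimed activity label (kept for config-driven axis
#'   overrides; the default power rule is activity-agnostic).
#' @param control A [wg_control()] list.
#' @param axis Optional override: `"x"`, `"y"` or `"z"`.
#' @return Numeric vector with attributes `rate` and `axis`.
#' @export
detection_signal <- function(series, activity, control = wg_control(),
                             axis = NULL) {
  stopifnot(inherits(series, "accel_series"))
  if (is.null(series$rate)) stop("series must be uniformly sampled")
  .check_activity(activity)
  axes <- list(x = series$ax, y = series$ay, z = series$az)
  if (is.null(axis)) {
    pw <- vapply(axes, function(a) {
      pg <- .periodogram(a, series$rate)
      sum(pg$S[pg$freq >= 1 & pg$freq <= 3])
    }, numeric(1))
    axis <- names(axes)[which.max(pw)]  # which.max: ties -> lowest index
  } else if (!axis %in% c("x", "y", "z")) stop("axis must be x, y or z")
  x <- axes[[axis]]
  x <- x - mean(x)
  flt <- signal::butter(control$detect_order,
                        2 * control$detect_cutoff / series$rate, type = "low")
  x <- .pad_filter(x, flt, zero_phase = TRUE)
  x <- x - mean(x)
  structure(x, rate = series$rate, axis = axis)
}

#' Initial adaptive peak/valley thresholds
#'
#' `thp = 0.5 * max(a)` for every activity; `thv = 0.7 * min(a)` for arm
#' swinging and `0.5 * min(a)` otherwise (the deep arm-swing valley
#' tolerates a stricter coefficient). Requires a signed, zero-centred
#' signal.
#'
#' @param signal Detection-axis signal (baseline removed).
#' @param activity Activity label.
#' @param control A [wg_control()] list.
#' @return List with elements `thp` (> 0) and `thv` (< 0).
#' @export
init_thresholds <- function(signal, activity, control = wg_control()) {
  .check_activity(activity)
  mx <- max(signal); mn <- min(signal)
  if (mx <= 0 || mn >= 0)
    stop("signal is not oscillatory around zero (need min < 0 < max)")
  cv <- if (activity == "swinging") control$thv_coef_swing else
    control$thv_coef_other
  list(thp = control$thp_coef * mx, thv = cv * mn)
}

#' Threshold-based peak and valley detection
#'
#' Peaks are local maxima with value `>= thp`; valleys local minima with
#' value `<= thv`. Extrema of the same kind closer than `min_separation`
#' samples keep only the more extreme one. When at least two valleys are
#' found, the mean valley spacing `mu_d` and the abnormal interval
#' `Ab_in = 1.3 * mu_d` are attached.
#'
#' @param signal Detection-axis signal.
#' @param thresholds List with `thp` and `thv` (see [init_thresholds()]).
#' @param min_separation Minimum peak spacing in samples.
#' @param valley_separation Minimum valley spacing in samples (defaults to
#'   `min_separation`); see [wg_control()] for why valleys are spaced more
#'   strictly in the pipeline.
#' @param control A [wg_control()] list (abnormal-interval factor).
#' @return List with `valleys`, `peaks` (strictly increasing sample
#'   indices, 1-based), `mu_d` and `abin` (samples; `NA` with < 2 valleys).
#' @export
find_extrema <- function(signal, thresholds, min_separation = 1L,
                         valley_separation = min_separation,
                         control = wg_control()) {
  pk <- .local_maxima(signal)
  pk <- pk[signal[pk] >= thresholds$thp]
  vl <- .local_minima(signal)
  vl <- vl[signal[vl] <= thresholds$thv]
  pk <- .enforce_separation(pk, signal[pk], min_separation)
  vl <- .enforce_separation(vl, -signal[vl], valley_separation)
  mu_d <- if (length(vl) >= 2L) mean(diff(vl)) else NA_real_
  list(valleys = vl, peaks = pk, mu_d = mu_d,
       abin = control$abin_factor * mu_d)
}

#' Minimum correction: recover missed valleys
#'
#' Any gap between adjacent detected valleys wider than the abnormal
#' interval is taken to hide a missed valley. Inside each such gap the
#' valley threshold is relaxed geometrically toward zero
#' (`thv <- relax_factor * thv`, the only direction that admits shallower
#' valleys) until a valid candidate appears: a local minimum below the
#' relaxed threshold, at least `mu_d / 4` samples from both gap endpoints,
#' with `|a|` at or above the noise floor. Among several candidates the one
#' with the largest absolute acceleration is accepted. A gap still empty
#' after `relax_max_iter` relaxations is left uncorrected and logged.
#'
#' @param signal Detection-axis signal.
#' @param extrema Result of [find_extrema()] with >= 2 valleys.
#' @param thresholds Initial thresholds from [init_thresholds()].
#' @param control A [wg_control()] list.
#' @return List with `valleys` (corrected, strictly increasing) and `log`
#'   (counts: `valleys_added`, `gaps_uncorrected`).
#' @export
minimum_correction <- function(signal, extrema, thresholds,
                               control = wg_control()) {
  vl <- extrema$valleys
  if (length(vl) < 2L) stop("minimum correction needs at least 2 valleys")
  mu_d <- extrema$mu_d
  abin <- extrema$abin
  minima <- .local_minima(signal)
  added <- 0L
  given_up <- matrix(numeric(0), ncol = 2L)
  repeat {
    gaps <- which(diff(vl) > abin)
    gaps <- gaps[!vapply(gaps, function(g)
      any(given_up[, 1] == vl[g] & given_up[, 2] == vl[g + 1L]), logical(1))]
    if (!length(gaps)) break
    g <- gaps[1L]
    lo <- vl[g]; hi <- vl[g + 1L]
    cand <- minima[minima > lo & minima < hi]
    thv_r <- thresholds$thv
    found <- NA_integer_
    for (it in seq_len(control$relax_max_iter)) {
      ok <- cand[signal[cand] <= thv_r &
                   abs(signal[cand]) >= control$noise_floor &
                   (cand - lo) >= mu_d / 4 & (hi - cand) >= mu_d / 4]
      if (length(ok)) {
        found <- ok[which.max(abs(signal[ok]))]
        break
      }
      thv_r <- control$relax_factor * thv_r
    }
    if (is.na(found)) {
      given_up <- rbind(given_up, c(lo, hi))
    } else {
      vl <- sort(unique(c(vl, found)))
      added <- added + 1L
    }
  }
  list(valleys = vl,
       log = c(valleys_added = added, gaps_uncorrected = nrow(given_up)))
}

#' Misclassification feedback from the peaks-per-interval statistic
#'
#' Each pair of adjacent valleys bounds a reference interval; arm swinging
#' puts two peaks in it, the centre-of-mass activities one. If the claimed
#' activity is swinging but intervals holding exactly one peak strictly
#' exceed half of all intervals, the trial is routed back to the stage-2
#' classifier (`"to_stage2"`); if a centre-of-mass activity is claimed but
#' two-peak intervals strictly exceed half, it is routed to the swing
#' detector (`"to_swing_detector"`); otherwise `"none"`.
#'
#' @param valleys Corrected valley indices (>= 2).
#' @param peaks Detected peak indices.
#' @param claimed_activity The activity label under which detection ran.
#' @param control A [wg_control()] list (majority fraction).
#' @return `"none"`, `"to_stage2"` or `"to_swing_detector"`.
#' @export
check_misclassification <- function(valleys, peaks, claimed_activity,
                                    control = wg_control()) {
  .check_activity(claimed_activity)
  if (length(valleys) < 2L) stop("need at least 2 valleys")
  counts <- vapply(seq_len(length(valleys) - 1L), function(i)
    sum(peaks > valleys[i] & peaks < valleys[i + 1L]), integer(1))
  n_int <- length(counts)
  thr <- control$feedback_majority * n_int
  if (claimed_activity == "swinging") {
    if (sum(counts == 1L) > thr) "to_stage2" else "none"
  } else {
    if (sum(counts == 2L) > thr) "to_swing_detector" else "none"
  }
}

#' Maximum correction: recover missed and prune spurious peaks
#'
#' Every reference interval should hold `m` peaks: two for arm swinging,
#' one otherwise. An interval with fewer gets a re-detection pass in which
#' the peak threshold is lowered to the larger of its two bounding valleys'
#' acceleration values (candidates below the noise floor stay excluded); an
#' interval with more keeps the `m` largest. Intervals the signal cannot
#' fill are logged as deficits.
#'
#' @param signal Detection-axis signal.
#' @param valleys Corrected valley indices (>= 2).
#' @param peaks Initially detected peak indices.
#' @param activity Activity label (decides `m`).
#' @param control A [wg_control()] list.
#' @return List with `peaks` (corrected, strictly increasing, all inside
#'   reference intervals) and `log` (counts: `peaks_added`, `peaks_pruned`,
#'   `deficits`).
#' @export
maximum_correction <- function(signal, valleys, peaks, activity,
                               control = wg_control()) {
  .check_activity(activity)
  if (length(valleys) < 2L) stop("need at least 2 valleys")
  m <- if (activity == "swinging") 2L else 1L
  maxima <- .local_maxima(signal)
  out <- integer(0)
  added <- pruned <- deficits <- 0L
  for (i in seq_len(length(valleys) - 1L)) {
    lo <- valleys[i]; hi <- valleys[i + 1L]
    inside <- peaks[peaks > lo & peaks < hi]
    if (length(inside) < m) {
      thr <- max(signal[lo], signal[hi])
      cand <- maxima[maxima > lo & maxima < hi &
                       signal[maxima] > thr &
                       abs(signal[maxima]) >= control$noise_floor]
      cand <- setdiff(cand, inside)
      need <- m - length(inside)
      if (length(cand)) {
        take <- cand[order(signal[cand], decreasing = TRUE)][
          seq_len(min(need, length(cand)))]
        inside <- sort(c(inside, take))
        added <- added + length(take)
      }
    }
    if (length(inside) > m) {
      keep <- inside[order(signal[inside], decreasing = TRUE)][seq_len(m)]
      pruned <- pruned + length(inside) - m
      inside <- sort(keep)
    }
    if (length(inside) < m) deficits <- deficits + (m - length(inside))
    out <- c(out, inside)
  }
  list(peaks = sort(unique(out)),
       log = c(peaks_added = added, peaks_pruned = pruned,
               deficits = deficits))
}

#' Detect step events in one trial
#'
#' Runs the full activity-conditioned detector on a preprocessed series:
#' detection-axis selection and 5 Hz refiltering, adaptive thresholds,
#' threshold-based extremum search, minimum correction of valleys,
#' misclassification feedback, and maximum correction of peaks. Each
#' corrected peak is one step. For swinging, the valley-to-valley interval
#' (one arm half-cycle, two steps) is split at the midpoint between its two
#' peaks to give per-step durations; a centre-of-mass step spans its whole
#' reference interval.
#'
#' If the peaks-per-interval statistic contradicts the claimed activity the
#' outcome carries a feedback signal and no steps; the caller rereoutes the
#' trial (see [run_trial()]).
#'
#' @param series A uniform, preprocessed `accel_series` (15 Hz-filtered;
#'   baseline need not be removed -- detection removes it per axis).
#' @param activity Claimed activity label.
#' @param control A [wg_control()] list.
#' @param corrections Apply minimum/maximum correction (default `TRUE`;
#'   `FALSE` keeps only the raw thresholded extrema, for ablation).
#' @param feedback Check the peaks-per-interval statistic against the
#'   claimed activity (default `TRUE`). `FALSE` forces detection under the
#'   claimed label, used after a trial has already been rerouted once.
#' @param axis Optional detection-axis override.
#' @return An object of class `step_detection`: list with `steps` (list of
#'   step events: `peak`, `valley_before`, `valley_after`, `duration`,
#'   `slice` (n x 3 matrix of the tri-axial acceleration over the step),
#'   `det` (detection-axis slice), `rate`), `feedback`, `corrections_log`,
#'   `valleys`, `peaks`, `thresholds`, `axis`, `activity`, `rate`.
#' @export
detect_steps <- function(series, activity, control = wg_control(),
                         corrections = TRUE, feedback = TRUE, axis = NULL) {
  .check_activity(activity)
  sig <- detection_signal(series, activity, control, axis = axis)
  rate <- attr(sig, "rate")
  th <- init_thresholds(sig, activity, control)
  ## expected step period from the dominant gait-band frequency
  pg <- .periodogram(as.numeric(sig), rate)
  band <- pg$freq >= 1 & pg$freq <= 3
  fdom <- if (any(band) && max(pg$S[band]) > 0)
    pg$freq[band][which.max(pg$S[band])] else 2
  min_sep <- max(1L, round(control$min_sep_frac * rate / fdom))
  valley_sep <- max(1L, round(control$valley_sep_frac * rate / fdom))
  ext <- find_extrema(as.numeric(sig), th, min_sep, valley_sep, control)
  if (length(ext$valleys) < 2L)
    stop("trial too short: fewer than 2 valleys detected")
  clog <- c(valleys_added = 0L, gaps_uncorrected = 0L,
            peaks_added = 0L, peaks_pruned = 0L, deficits = 0L)
  valleys <- ext$valleys
  if (corrections) {
    mc <- minimum_correction(as.numeric(sig), ext, th, control)
    valleys <- mc$valleys
    clog[names(mc$log)] <- mc$log
  }
  fb <- if (feedback)
    check_misclassification(valleys, ext$peaks, activity, control) else "none"
  if (fb != "none") {
    return(structure(list(steps = list(), feedback = fb,
                          corrections_log = clog, valleys = valleys,
                          peaks = ext$peaks, thresholds = th,
                          axis = attr(sig, "axis"), activity = activity,
                          rate = rate, signal = as.numeric(sig)),
                     class = "step_detection"))
  }
  peaks <- ext$peaks
  if (corrections) {
    xc <- maximum_correction(as.numeric(sig), valleys, peaks, activity,
                             control)
    peaks <- xc$peaks
    clog[names(xc$log)] <- xc$log
  } else {
    peaks <- peaks[peaks > valleys[1] & peaks < valleys[length(valleys)]]
  }
  base <- remove_baseline(series)
  tri <- cbind(ax = base$ax, ay = base$ay, az = base$az)
  sigv <- as.numeric(sig)
  steps <- list()
  mstep <- function(pk, lo, hi) {
    list(peak = pk, valley_before = lo, valley_after = hi,
         duration = (hi - lo) / rate,
         slice = tri[lo:(hi - 1L), , drop = FALSE],
         det = sigv[lo:(hi - 1L)], rate = rate)
  }
  for (i in seq_len(length(valleys) - 1L)) {
    lo <- valleys[i]; hi <- valleys[i + 1L]
    inside <- peaks[peaks > lo & peaks < hi]
    if (!length(inside)) next
    if (activity == "swinging" && length(inside) == 2L) {
      mid <- as.integer(floor((inside[1] + inside[2]) / 2))
      steps <- c(steps, list(mstep(inside[1], lo, mid),
                             mstep(inside[2], mid, hi)))
    } else {
      for (pk in inside) steps <- c(steps, list(mstep(pk, lo, hi)))
    }
  }
  structure(list(steps = steps, feedback = "none", corrections_log = clog,
                 valleys = valleys, peaks = peaks, thresholds = th,
                 axis = attr(sig, "axis"), activity = activity, rate = rate,
                 signal = sigv),
            class = "step_detection")
}

#' @export
print.step_detection <- function(x, ...) {
  cat(sprintf("<step_detection> activity %s (axis %s): %d steps, feedback %s\n",
              x$activity, x$axis, length(x$steps), x$feedback))
  if (any(x$corrections_log > 0)) {
    cl <- x$corrections_log[x$corrections_log > 0]
    cat("  corrections:", paste(names(cl), cl, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
summary.step_detection <- function(object, ...) {
  d <- vapply(object$steps, `[[`, numeric(1), "duration")
  cat(sprintf("Step detection (%s, axis %s)\n", object$activity, object$axis))
  cat(sprintf("  valleys %d, peaks %d, steps %d, feedback %s\n",
              length(object$valleys), length(object$peaks),
              length(object$steps), object$feedback))
  if (length(d))
    cat(sprintf("  step duration: mean %.3f s, range [%.3f, %.3f] s\n",
                mean(d), min(d), max(d)))
  invisible(object)
}
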