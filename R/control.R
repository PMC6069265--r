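#' Pipeline settings
#'
#' Collects every tunable of the walking-distance pipeline in one list, in
#' the style of `glm.control()`. The defaults are the method's standard
#' operating point; each can be overridden per call.
#'
#' @param resample_rate Uniform grid rate in Hz (default 50).
#' @param prefilter_cutoff,prefilter_order Anti-noise low-pass applied to the
#'   raw trace: 15 Hz, 10th-order Butterworth, zero-phase.
#' @param detect_cutoff,detect_order Second low-pass applied to the detection
#'   axis before peak/valley search: 5 Hz; a 4th-order filter is steep enough
#'   here and numerically comfortable at this cutoff.
#' @param window_size,window_overlap Feature window: 100 samples (2 s at
#'   50 Hz) with 50% overlap.
#' @param thp_coef Peak threshold coefficient: `thp = thp_coef * max(a)`.
#' @param thv_coef_swing,thv_coef_other Valley threshold coefficients:
#'   `thv = coef * min(a)`, 0.7 for arm swinging and 0.5 otherwise.
#' @param abin_factor Abnormal-interval factor: `Ab_in = 1.3 * mu_d` where
#'   `mu_d` is the mean spacing between detected valleys.
#' @param noise_floor Extremum candidates with `|a|` below this (m/s^2) are
#'   treated as noise (default 0.1).
#' @param relax_factor,relax_max_iter Valley-threshold relaxation schedule in
#'   the minimum correction: `thv <- relax_factor * thv` (toward zero, so
#'   shallower valleys are admitted), at most `relax_max_iter` times.
#' @param feedback_majority Fraction of reference intervals whose
#'   peaks-per-interval count must contradict the claimed activity before the
#'   trial is rerouted (strictly exceeded; default 0.5).
#' @param min_sep_frac Minimum peak separation as a fraction of the
#'   expected step period (default 0.25), preventing jitter double-counts.
#' @param valley_sep_frac Minimum valley separation as a fraction of the
#'   expected step period (default 0.4). Valleys are held to a stricter
#'   spacing than peaks: they define the reference intervals and the
#'   correction machinery can add but never remove a valley, whereas excess
#'   peaks are pruned per interval anyway.
#' @param degree Polynomial degree of the locally weighted K-factor
#'   regression (default 4).
#' @param bandwidth Gaussian kernel bandwidth in units of the step-velocity
#'   feature; `NULL` (default) uses Silverman's rule of thumb on the
#'   training velocities.
#' @param estimator_map Named character vector mapping each activity to its
#'   step-length estimator (`"weinberg"`, `"kim"` or `"tian"`). The default
#'   uses Tian for texting/calling/suitcase and Kim for pocket/swinging.
#' @param band_power_ratio If `TRUE`, window band powers are normalised by
#'   the total periodogram power (power *ratios*); default `FALSE` reports
#'   absolute band power.
#' @return A named list of class `wg_control`.
#' @export
wg_control <- function(resample_rate = 50,
                       prefilter_cutoff = 15, prefilter_order = 10L,
                       detect_cutoff = 5, detect_order = 4L,
                       window_size = 100L, window_overlap = 0.5,
                       thp_coef = 0.5, thv_coef_swing = 0.7,
                       thv_coef_other = 0.5,
                       abin_factor = 1.3, noise_floor = 0.1,
                       relax_factor = 0.8, relax_max_iter = 10L,
                       feedback_majority = 0.5, min_sep_frac = 0.25,
                       valley_sep_frac = 0.4,
                       degree = 4L, bandwidth = NULL,
                       estimator_map = c(texting = "tian", calling = "tian",
                                         suitcase = "tian", pocket = "kim",
                                         swinging = "kim"),
                       band_power_ratio = FALSE) {
  stopifnot(resample_rate > 0, prefilter_cutoff > 0, detect_cutoff > 0,
            thp_coef > 0, thv_coef_swing > 0, thv_coef_other > 0,
            abin_factor >= 1, noise_floor >= 0,
            relax_factor > 0, relax_factor < 1, relax_max_iter >= 1,
            feedback_majority > 0, feedback_majority < 1,
            min_sep_frac > 0, valley_sep_frac > 0, degree >= 0)
  if (!all(wg_activities %in% names(estimator_map)))
    stop("estimator_map must name all five activities")
  if (!all(estimator_map %in% c("weinberg", "kim", "tian")))
    stop("estimator_map values must be weinberg/kim/tian")
  structure(list(resample_rate = resample_rate,
                 prefilter_cutoff = prefilter_cutoff,
                 prefilter_order = as.integer(prefilter_order),
                 detect_cutoff = detect_cutoff,
                 detect_order = as.integer(detect_order),
                 window_size = as.integer(window_size),
                 window_overlap = window_overlap,
                 thp_coef = thp_coef, thv_coef_swing = thv_coef_swing,
                 thv_coef_other = thv_coef_other,
                 abin_factor = abin_factor, noise_floor = noise_floor,
                 relax_factor = relax_factor,
                 relax_max_iter = as.integer(relax_max_iter),
                 feedback_majority = feedback_majority,
                 min_sep_frac = min_sep_frac,
                 valley_sep_frac = valley_sep_frac,
                 degree = as.integer(degree), bandwidth = bandwidth,
                 estimator_map = estimator_map,
                 band_power_ratio = band_power_ratio),
            class = "wg_control")
}

#' The five wrist activities
#'
#' Closed label set used throughout the package: phone texting, phone
#' calling, hand in pocket, suitcase carrying and hand (arm) swinging during
#' walking. The first four are centre-of-mass activities whose wrist
#' acceleration shows one peak between consecutive valleys; swinging shows
#' two.
#' @export
wg_activities <- c("texting", "calling", "pocket", "suitcase", "swinging")

.check_activity <- function(activity) {
  if (length(activity) != 1L || !activity %in% wg_activities)
    stop("activity must be one of: ", paste(wg_activities, collapse = ", "))
  activity
}
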