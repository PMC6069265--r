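## Frozen waveform constants.
## Swing archetype: g(theta) = sin(theta) + 0.45 * cos(2*theta), normalised
## by its depth 1.45. Per 2*pi cycle this has two equal maxima (0.502 at
## theta = 0.1875*pi and 0.8125*pi), one deep minimum (-1 at 1.5*pi) and a
## secondary stationary point that stays positive, so the one-valley /
## two-peaks-per-cycle structure of wrist arm swing is exact by
## construction. Centre-of-mass archetype: -cos(theta), one peak between
## consecutive valleys.
.SWING_R <- 0.45
.SWING_NORM <- 1.45
.SWING_VALLEY_PHASE <- 1.5 * pi
.SWING_PEAK_PHASES <- c(0.1875, 0.8125) * pi

## Centre-of-mass archetype: a fundamental with second and third harmonics
## shaped so the cycle is asymmetric the way real heel-strike-driven torso
## acceleration is. Two consequences that a pure sinusoid lacks: the net
## velocity change over one step is substantial (so the per-step
## mean-velocity feature genuinely tracks walking speed, and is robust to
## one-sample jitter in the detected valley position), and the peak is
## sharper than the valley. Still exactly one peak and one valley per
## cycle; harmonic weights stay below the point where secondary extrema
## appear, with margin for the 5 Hz refilter's harmonic attenuation.
.COM_B2 <- 0.475
.COM_P2 <- 5 * pi / 16
.COM_B3 <- 0.175
.COM_P3 <- 19 * pi / 16
.com_wave <- function(theta) {
  -cos(theta) + .COM_B2 * sin(2 * theta + .COM_P2) +
    .COM_B3 * sin(3 * theta + .COM_P3)
}
.com_extrema <- local({
  th <- seq(0, 2 * pi, length.out = 4096L)
  a <- .com_wave(th)
  iv <- which.min(a); ip <- which.max(a)
  dd <- 2 * pi / 4095
  vall <- stats::optimize(.com_wave, c(th[iv] - dd, th[iv] + dd),
                          tol = 1e-12)
  peak <- stats::optimize(.com_wave, c(th[ip] - dd, th[ip] + dd),
                          maximum = TRUE, tol = 1e-12)
  list(valley_phase = vall$minimum, peak_phase = peak$maximum,
       depth = abs(vall$objective))
})
.COM_VALLEY_PHASE <- .com_extrema$valley_phase
.COM_PEAK_PHASE <- .com_extrema$peak_phase
.COM_NORM <- .com_extrema$depth  # amplitude parameter = valley depth

## Per-activity detection axis and device-orientation gravity direction
## (unit vectors; distinct orientations are what make the four
## centre-of-mass activities separable by the moment features).
.ACTIVITY_AXIS <- c(texting = "x", calling = "y", pocket = "z",
                    suitcase = "x", swinging = "y")
.ACTIVITY_GRAVITY <- list(
  texting  = c(0.20, 0.25, 0.95),
  calling  = c(0.85, 0.30, 0.45),
  pocket   = c(0.10, 0.90, 0.42),
  suitcase = c(0.62, 0.62, 0.48),
  swinging = c(0.35, 0.10, 0.93))

.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Specification of one synthetic gait trial
#'
#' Collects and validates the generator parameters. Defaults emulate the
#' study design this generator stands in for: 62.5 Hz wrist recordings of
#' 20 m walks, amplitudes of a few m/s^2, mild per-step length variability.
#'
#' @param activity One of [wg_activities].
#' @param step_freq Step frequency in Hz, within the human walking band
#'   1.2-2.6.
#' @param n_steps Number of steps (>= 4; even for swinging, which packs two
#'   steps per arm cycle). Default: steps needed for 20 m at
#'   `mean_step_length`.
#' @param amplitude Oscillation amplitude of the detection axis in m/s^2
#'   (valley depth). Default 2, or 4 for swinging -- the arm swings harder
#'   than the torso bobs.
#' @param noise_sd White measurement-noise SD in m/s^2 (default 0.15; keep
#'   below `amplitude / 3` for a clean preset).
#' @param height_m Subject height in metres.
#' @param mean_step_length Mean true step length in metres (default 0.7
#'   scaled by `step_freq / 1.8`).
#' @param step_length_cv Coefficient of variation of per-step lengths.
#' @param artifact_rates Named fractions `valley_attenuation`,
#'   `peak_attenuation`, `spurious_extrema` handed to [inject_artifacts()]
#'   by [generate_trial()].
#' @param seed Integer RNG seed; trials are fully deterministic given it.
#' @return A list of class `synthetic_trial_spec`.
#' @export
synthetic_trial_spec <- function(activity, step_freq = 1.8, n_steps = NULL,
                                 amplitude = NULL, noise_sd = 0.15,
                                 height_m = 1.7, mean_step_length = NULL,
                                 step_length_cv = 0.05,
                                 artifact_rates = c(valley_attenuation = 0,
                                                    peak_attenuation = 0,
                                                    spurious_extrema = 0),
                                 seed = 1L) {
  .check_activity(activity)
  if (step_freq < 1.2 || step_freq > 2.6)
    stop("step_freq must lie in the walking band [1.2, 2.6] Hz")
  if (is.null(mean_step_length))
    mean_step_length <- 0.7 * step_freq / 1.8
  if (mean_step_length <= 0) stop("mean_step_length must be positive")
  if (is.null(n_steps)) {
    n_steps <- round(20 / mean_step_length)
    if (activity == "swinging") n_steps <- 2L * round(10 / mean_step_length)
  }
  n_steps <- as.integer(n_steps)
  if (n_steps < 4L) stop("n_steps must be >= 4")
  if (activity == "swinging" && n_steps %% 2L != 0L)
    stop("swinging needs an even n_steps (two steps per arm cycle)")
  if (is.null(amplitude))
    amplitude <- if (activity == "swinging") 4 else 2
  if (amplitude <= 0) stop("amplitude must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (step_length_cv < 0 || step_length_cv >= 0.5)
    stop("step_length_cv must be in [0, 0.5)")
  ar <- c(valley_attenuation = 0, peak_attenuation = 0, spurious_extrema = 0)
  ar[names(artifact_rates)] <- artifact_rates
  if (any(ar < 0 | ar > 1)) stop("artifact rates must be in [0, 1]")
  structure(list(activity = activity, step_freq = step_freq,
                 n_steps = n_steps, amplitude = amplitude,
                 noise_sd = noise_sd, height_m = height_m,
                 mean_step_length = mean_step_length,
                 step_length_cv = step_length_cv, artifact_rates = ar,
                 seed = as.integer(seed)),
            class = "synthetic_trial_spec")
}

## Smooth AR(1) off-axis noise, stationary variance sd^2.
.ar1_noise <- function(n, sd, phi = 0.95) {
  as.numeric(stats::filter(stats::rnorm(n, 0, sd * sqrt(1 - phi^2)),
                           phi, method = "recursive"))
}

#' Generate one synthetic wrist-acceleration trial
#'
#' Builds a 62.5 Hz tri-axial trace (with 1 ms timestamp jitter, so the
#' resampler is exercised) whose detection axis carries the activity's
#' archetype waveform: a sinusoid at the step frequency for the
#' centre-of-mass activities, or the two-peaks-per-cycle arm-swing waveform
#' at half the step frequency for swinging. The first and last waveform
#' valleys are padded by a quarter cycle so every ground-truth valley is an
#' interior extremum. Per-step lengths are drawn around the spec mean with
#' the given CV and rescaled to the exact total; the waveform amplitude is
#' modulated per step in proportion to step length, which induces the
#' learnable relation between the step-velocity feature and the K-factor.
#' Gravity is added along a per-activity orientation and the off axes carry
#' low-amplitude smooth noise. Fully deterministic given the spec seed.
#'
#' @param spec A [synthetic_trial_spec()].
#' @return An object of class `synthetic_trial`: list with `series` (raw
#'   `accel_series`), `truth` (activity, detection axis, step times, step
#'   lengths, total distance, valley times, n_steps, height, step_freq,
#'   per-axis gravity) and `spec`.
#' @export
generate_trial <- function(spec) {
  stopifnot(inherits(spec, "synthetic_trial_spec"))
  .with_seed(spec$seed, {
    f <- spec$step_freq
    n <- spec$n_steps
    swing <- spec$activity == "swinging"
    ## per-step true lengths, rescaled to the exact total
    L <- spec$mean_step_length *
      pmin(pmax(1 + spec$step_length_cv * stats::rnorm(n), 0.4), 1.6)
    L <- L * (n * spec$mean_step_length) / sum(L)
    fw <- if (swing) f / 2 else f      # waveform fundamental
    pad <- 0.25 / fw
    n_cyc <- if (swing) n %/% 2L else n
    total_t <- n_cyc / fw + 2 * pad
    raw_rate <- 62.5
    ns <- floor(total_t * raw_rate) + 1L
    t <- sort((0:(ns - 1L)) / raw_rate + stats::rnorm(ns, 0, 0.001))
    t <- t - t[1]
    if (swing) {
      theta <- 2 * pi * fw * (t - pad) + .SWING_VALLEY_PHASE
      core <- (sin(theta) + .SWING_R * cos(2 * theta)) / .SWING_NORM
      valley_t <- pad + (0:n_cyc) / fw
      peak_t <- as.numeric(t(outer((1:n_cyc) * 2 * pi + rep(0, n_cyc),
                                   .SWING_PEAK_PHASES, `+`)))
      peak_t <- pad + (peak_t - .SWING_VALLEY_PHASE) / (2 * pi * fw)
      cyc_len <- (L[seq(1, n, by = 2)] + L[seq(2, n, by = 2)]) / 2
      env_t <- pad + ((1:n_cyc) - 0.5) / fw
      env_a <- spec$amplitude * cyc_len / mean(cyc_len)
    } else {
      theta <- 2 * pi * f * (t - pad) + .COM_VALLEY_PHASE
      core <- .com_wave(theta) / .COM_NORM
      peak_off <- ((.COM_PEAK_PHASE - .COM_VALLEY_PHASE) %% (2 * pi)) /
        (2 * pi)
      valley_t <- pad + (0:n) / f
      peak_t <- pad + ((1:n) - 1 + peak_off) / f
      env_t <- peak_t
      env_a <- spec$amplitude * L / mean(L)
    }
    env <- stats::approx(env_t, env_a, xout = t, rule = 2)$y
    det <- env * core + stats::rnorm(ns, 0, spec$noise_sd)
    axis <- .ACTIVITY_AXIS[[spec$activity]]
    gdir <- .ACTIVITY_GRAVITY[[spec$activity]]
    gvec <- 9.81 * gdir / sqrt(sum(gdir^2))
    names(gvec) <- c("x", "y", "z")
    sig <- list(x = numeric(ns), y = numeric(ns), z = numeric(ns))
    for (ax in c("x", "y", "z")) {
      sig[[ax]] <- if (ax == axis) det else
        .ar1_noise(ns, 0.04 * spec$amplitude, phi = 0.9)
      sig[[ax]] <- sig[[ax]] + gvec[[ax]]
    }
    trial <- structure(
      list(series = accel_series(t, sig$x, sig$y, sig$z),
           truth = list(activity = spec$activity, axis = axis,
                        step_times = sort(peak_t), step_lengths = L,
                        total_distance = sum(L), valley_times = valley_t,
                        n_steps = n, height = spec$height_m, step_freq = f,
                        gravity = gvec),
           spec = spec),
      class = "synthetic_trial")
    if (any(spec$artifact_rates > 0))
      trial <- inject_artifacts(trial, spec$artifact_rates,
                                seed = spec$seed + 7919L)
    trial
  })
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_trial> %s: %d steps at %.2f Hz, %.2f m, ",
                     "axis %s, %d raw samples\n"),
              x$truth$activity, x$truth$n_steps, x$truth$step_freq,
              x$truth$total_distance, x$truth$axis, length(x$series$t)))
  invisible(x)
}

## Raised-cosine multiplicative attenuation of the oscillatory component
## around time tc: factor lambda at the centre, 1 at +/- tau.
.attenuate <- function(x, t, tc, tau, lambda) {
  i <- which(abs(t - tc) <= tau)
  w <- 0.5 * (1 + cos(pi * (t[i] - tc) / tau))
  x[i] <- x[i] * (1 - (1 - lambda) * w)
  x
}

#' Inject detection artifacts into a synthetic trial
#'
#' Emulates the real-signal failure modes the correction algorithms exist
#' for, without touching the ground truth: a seeded fraction of interior
#' valleys and of peaks is attenuated below the initial detection
#' thresholds (to 30% of their depth, smoothly, staying above the 0.1
#' m/s^2 noise floor), and spurious super-threshold bumps can be added
#' inside reference intervals.
#'
#' @param trial A `synthetic_trial`.
#' @param rates Named fractions: `valley_attenuation` (of interior
#'   valleys), `peak_attenuation` (of peaks), `spurious_extrema` (of
#'   reference intervals). Counts are `round(rate * n)`, so e.g. rate 0.1
#'   on 20 interior valleys attenuates exactly 2.
#' @param seed Integer seed for the artifact draw.
#' @return The modified `synthetic_trial` (truth unchanged).
#' @export
inject_artifacts <- function(trial, rates, seed = 1L) {
  stopifnot(inherits(trial, "synthetic_trial"))
  ar <- c(valley_attenuation = 0, peak_attenuation = 0, spurious_extrema = 0)
  ar[names(rates)] <- rates
  if (all(ar == 0)) return(trial)
  tr <- trial$truth
  fw <- if (tr$activity == "swinging") tr$step_freq / 2 else tr$step_freq
  s <- trial$series
  t <- s$t
  axis <- tr$axis
  col <- paste0("a", axis)
  x <- s[[col]] - tr$gravity[[axis]]
  lambda <- 0.3
  .with_seed(seed, {
    vint <- tr$valley_times[-c(1L, length(tr$valley_times))]
    nv <- round(ar[["valley_attenuation"]] * length(vint))
    if (nv > 0) {
      for (tc in sample(vint, nv))
        x <- .attenuate(x, t, tc, 0.25 / fw, lambda)
    }
    np <- round(ar[["peak_attenuation"]] * length(tr$step_times))
    if (np > 0) {
      tau_p <- if (tr$activity == "swinging") 0.12 / fw else 0.25 / fw
      for (tc in sample(tr$step_times, np))
        x <- .attenuate(x, t, tc, tau_p, lambda)
    }
    nsp <- round(ar[["spurious_extrema"]] * (length(tr$valley_times) - 1L))
    if (nsp > 0) {
      amp <- 1.5 * trial$spec$amplitude
      ## bump centred between a valley and the following peak, wide enough
      ## to survive the 5 Hz detection refilter
      base_peaks <- if (tr$activity == "swinging")
        tr$step_times[seq(2, length(tr$step_times), by = 2)] else
          tr$step_times
      for (tc in sample(base_peaks, min(nsp, length(base_peaks)))) {
        tv_prev <- max(tr$valley_times[tr$valley_times < tc])
        cc <- tv_prev + 0.45 * (tc - tv_prev)
        tau <- 0.35 * (tc - tv_prev)
        i <- which(abs(t - cc) <= tau)
        x[i] <- x[i] + amp * 0.5 * (1 + cos(pi * (t[i] - cc) / tau))
      }
    }
  })
  s[[col]] <- x + tr$gravity[[axis]]
  trial$series <- accel_series(s$t, s$ax, s$ay, s$az, rate = s$rate)
  trial
}

#' Generate a balanced synthetic walking dataset
#'
#' A full factorial design over subjects, the five activities, speed levels
#' and repetitions, emulating repeated 20 m walks at several speeds:
#' per-trial step counts are chosen so that the true total distance is
#' exactly 20 m, mean step length scales with speed and (mildly, as the
#' square root) with subject height, and the waveform amplitude grows with
#' the square of the speed ratio so that faster walking produces both
#' larger accelerations and distinct step-velocity distributions for the
#' speed-band analysis.
#'
#' @param n_subjects Number of subjects; heights are drawn uniformly in
#'   1.5-1.9 m.
#' @param trials_per_activity Repetitions per subject x activity x speed
#'   cell.
#' @param speed_levels Step frequencies in Hz (default `c(1.4, 1.8, 2.2)`).
#' @param seed Integer seed; the dataset is bit-reproducible given it.
#' @param noise_sd Measurement noise SD handed to every trial.
#' @param artifact_rates Optional artifact rates applied to every trial.
#' @return An object of class `wg_dataset`: list with `trials` (list of
#'   `synthetic_trial`) and `meta` (`data.frame`: `trial_id`, `subject`,
#'   `activity`, `height_m`, `true_distance_m`, `n_steps`, `step_freq`,
#'   `seed`).
#' @export
generate_dataset <- function(n_subjects = 2L, trials_per_activity = 2L,
                             speed_levels = c(1.4, 1.8, 2.2), seed = 1L,
                             noise_sd = 0.15,
                             artifact_rates = c(valley_attenuation = 0,
                                                peak_attenuation = 0,
                                                spurious_extrema = 0)) {
  stopifnot(n_subjects >= 1, trials_per_activity >= 1,
            length(speed_levels) >= 1)
  heights <- .with_seed(seed, stats::runif(n_subjects, 1.5, 1.9))
  trials <- list()
  meta <- list()
  id <- 0L
  for (s in seq_len(n_subjects)) for (a in wg_activities)
    for (f in speed_levels) for (r in seq_len(trials_per_activity)) {
      id <- id + 1L
      h <- heights[s]
      trial_seed <- (abs(seed) %% 2000000L) * 1000L + id
      ## step length grows sublinearly with cadence (fast walkers gain
      ## speed mostly from cadence) and mildly with height
      msl <- 0.7 * (f / 1.8)^0.7 * sqrt(h / 1.7)
      n_steps <- if (a == "swinging") 2L * max(2L, round(10 / msl)) else
        max(4L, round(20 / msl))
      msl <- 20 / n_steps
      ## oscillation acceleration goes as omega^2 x displacement and the
      ## displacement grows with step length, hence ~ cadence^2.7
      amp <- (if (a == "swinging") 4 else 2) * (f / 1.8)^2.7
      spec <- synthetic_trial_spec(
        activity = a, step_freq = f, n_steps = n_steps, amplitude = amp,
        noise_sd = noise_sd, height_m = h, mean_step_length = msl,
        artifact_rates = artifact_rates, seed = trial_seed)
      trials[[id]] <- generate_trial(spec)
      meta[[id]] <- data.frame(trial_id = id, subject = s, activity = a,
                               height_m = h, true_distance_m = 20,
                               n_steps = n_steps, step_freq = f,
                               seed = trial_seed)
    }
  structure(list(trials = trials, meta = do.call(rbind, meta)),
            class = "wg_dataset")
}

#' @export
print.wg_dataset <- function(x, ...) {
  cat(sprintf("<wg_dataset> %d trials: %d subject(s) x %d activities x %d speed(s)\n",
              nrow(x$meta), length(unique(x$meta$subject)),
              length(unique(x$meta$activity)),
              length(unique(x$meta$step_freq))))
  invisible(x)
}
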