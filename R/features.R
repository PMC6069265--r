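#' Sliding feature windows
#'
#' Cuts a uniform series into windows of `size` samples advancing by
#' `size * (1 - overlap)` samples; trailing samples that do not fill a whole
#' window are dropped. The defaults (100 samples, 50% overlap) give 2-s
#' windows at 50 Hz.
#'
#' @param series A uniform `accel_series`.
#' @param size Window length in samples (>= 2).
#' @param overlap Overlap fraction in `[0, 1)`; the hop `size * (1 - overlap)`
#'   must be a whole number of samples.
#' @return A list of windows; each window is an `n x 3` matrix with columns
#'   `ax`, `ay`, `az` and attributes `start` (0-based sample index of the
#'   first sample) and `rate`.
#' @export
sliding_windows <- function(series, size = 100L, overlap = 0.5) {
  stopifnot(inherits(series, "accel_series"))
  if (is.null(series$rate)) stop("series must be uniformly sampled")
  size <- as.integer(size)
  if (size < 2L) stop("window size must be >= 2")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  hop <- size * (1 - overlap)
  if (abs(hop - round(hop)) > 1e-9 || round(hop) < 1)
    stop("size * (1 - overlap) must be a positive integer")
  hop <- as.integer(round(hop))
  n <- length(series$t)
  if (n < size) stop("series shorter than one window (", n, " < ", size, ")")
  starts <- seq.int(0L, n - size, by = hop)
  lapply(starts, function(s) {
    w <- cbind(ax = series$ax[(s + 1L):(s + size)],
               ay = series$ay[(s + 1L):(s + size)],
               az = series$az[(s + 1L):(s + size)])
    attr(w, "start") <- s
    attr(w, "rate") <- series$rate
    w
  })
}

#' Signal magnitude area of a window
#'
#' `SMA = (1/n) * sum_i (|a_i^x| + |a_i^y| + |a_i^z|)`: the mean summed
#' absolute tri-axial acceleration, a standard overall-intensity feature.
#'
#' @param window An `n x 3` window matrix (see [sliding_windows()]).
#' @return A single non-negative number.
#' @export
sma <- function(window) {
  mean(abs(window[, 1L]) + abs(window[, 2L]) + abs(window[, 3L]))
}

#' Intensity of movement per axis
#'
#' Mean absolute successive difference of each axis, `(1/n) * sum_k
#' |a_(k+1) - a_k|` over the `n - 1` consecutive sample pairs: a jerk-like
#' measure of how fast the signal moves.
#'
#' @inheritParams sma
#' @return Named numeric vector `c(IM_x, IM_y, IM_z)`.
#' @export
intensity_of_movement <- function(window) {
  n <- nrow(window)
  if (n < 2L) stop("window must have at least 2 samples")
  d <- window[-1L, , drop = FALSE] - window[-n, , drop = FALSE]
  stats::setNames(colSums(abs(d)) / n, c("IM_x", "IM_y", "IM_z"))
}

#' Per-axis mean and population standard deviation
#'
#' @inheritParams sma
#' @return Named numeric vector `c(mu_x, mu_y, mu_z, sigma_x, sigma_y,
#'   sigma_z)`; sigma uses the population (1/n) convention.
#' @export
mean_std <- function(window) {
  n <- nrow(window)
  if (n < 2L) stop("window must have at least 2 samples")
  mu <- colMeans(window)
  sg <- sqrt(colMeans(sweep(window, 2L, mu)^2))
  stats::setNames(c(mu, sg), c("mu_x", "mu_y", "mu_z",
                               "sigma_x", "sigma_y", "sigma_z"))
}

## One-sided raw periodogram of a mean-removed signal.
## Returns frequencies 0..Nyquist and ordinates S_k = |X_k|^2 / n with the
## DC ordinate identically 0 (mean removed), so spectral features reflect
## motion rather than the gravity remnant.
.periodogram <- function(x, rate) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  kmax <- floor(n / 2)
  list(freq = (0:kmax) * rate / n,
       S = (Mod(X[1:(kmax + 1L)])^2) / n,
       total = sum(Mod(X)^2) / n)  # = sum((x - mean)^2) by Parseval
}

#' Average spectral energy of a window
#'
#' Per axis, the sum of squared discrete Fourier component magnitudes of the
#' mean-removed signal, normalised by the window length (by Parseval this
#' equals the time-domain energy `sum((a - mu)^2)`); AE is the mean of the
#' three axis energies. The DC component is excluded so the feature reflects
#' motion, not gravity.
#'
#' @inheritParams sma
#' @return A single non-negative number.
#' @export
average_energy <- function(window) {
  mean(apply(window, 2L, function(x) {
    X <- stats::fft(x - mean(x))
    sum(Mod(X)^2) / length(x)
  }))
}

#' Band power of one axis
#'
#' Trapezoid-style integral of the raw periodogram over `[fa, fb]`:
#' `p = (fb - fa) / (2 N) * (S(fa) + 2 * sum S(fk) + S(fb))` with `N` the
#' sampling frequency, `S` the periodogram of the mean-removed signal
#' (linearly interpolated at the band edges) and `fk` the periodogram
#' frequencies strictly inside the band.
#'
#' @param x Numeric vector: one axis of a window.
#' @param fa,fb Band edges in Hz, `0 <= fa < fb <= rate/2`.
#' @param rate Sampling rate in Hz.
#' @param ratio If `TRUE`, divide by the total periodogram power.
#' @return A single non-negative number.
#' @export
band_power <- function(x, fa, fb, rate, ratio = FALSE) {
  if (fa < 0 || fb > rate / 2 || fa >= fb)
    stop("band must satisfy 0 <= fa < fb <= rate/2")
  pg <- .periodogram(x, rate)
  Sedge <- stats::approx(pg$freq, pg$S, xout = c(fa, fb), rule = 2)$y
  inside <- pg$S[pg$freq > fa & pg$freq < fb]
  p <- (fb - fa) / (2 * rate) * (Sedge[1] + 2 * sum(inside) + Sedge[2])
  if (ratio) {
    tot <- sum(pg$S[-1L])
    p <- if (tot > 0) p / tot else 0
  }
  p
}

#' Peak power of one axis
#'
#' Total power of the five dominant frequencies: the sum of the 5 largest
#' one-sided periodogram ordinates, DC excluded.
#'
#' @inheritParams band_power
#' @return A single non-negative number.
#' @export
peak_power <- function(x, rate) {
  if (length(x) < 10L) stop("window too short for peak power")
  S <- .periodogram(x, rate)$S[-1L]
  sum(sort(S, decreasing = TRUE)[1:5])
}

#' Names of the 23 window features
#'
#' The feature vector is: average energy AE (1), signal magnitude area SMA
#' (1), intensity of movement per axis (3), per-axis mean (3) and standard
#' deviation (3), band power in 0-0.5, 0.5-1 and 1-5 Hz per axis (9) and
#' peak power per axis (3) -- 23 in total.
#' @export
wg_feature_names <- c(
  "AE", "SMA", "IM_x", "IM_y", "IM_z",
  "mu_x", "mu_y", "mu_z", "sigma_x", "sigma_y", "sigma_z",
  "bp_x_b1", "bp_x_b2", "bp_x_b3",
  "bp_y_b1", "bp_y_b2", "bp_y_b3",
  "bp_z_b1", "bp_z_b2", "bp_z_b3",
  "pp_x", "pp_y", "pp_z")

#' Extract the 23 features of one window
#'
#' @inheritParams sma
#' @param rate Sampling rate in Hz; taken from the window attribute when
#'   missing.
#' @param band_power_ratio Report band powers as ratios of total power.
#' @return Named numeric vector of length 23 (see [wg_feature_names]).
#' @export
extract_features <- function(window, rate = attr(window, "rate"),
                             band_power_ratio = FALSE) {
  if (is.null(rate)) stop("sampling rate required")
  bands <- list(c(0, 0.5), c(0.5, 1), c(1, 5))
  bp <- unlist(lapply(1:3, function(axis)
    vapply(bands, function(b)
      band_power(window[, axis], b[1], b[2], rate, ratio = band_power_ratio),
      numeric(1))))
  pp <- vapply(1:3, function(axis) peak_power(window[, axis], rate),
               numeric(1))
  fv <- c(average_energy(window), sma(window), intensity_of_movement(window),
          mean_std(window), bp, pp)
  stats::setNames(fv, wg_feature_names)
}

#' Feature matrix for a whole trial
#'
#' Windows the series and extracts the 23 features of every window.
#'
#' @param series A uniform (preprocessed) `accel_series`.
#' @param control A [wg_control()] list (window size/overlap, band-power
#'   convention).
#' @return A `windows x 23` numeric matrix with column names
#'   [wg_feature_names] and attribute `start` holding the 0-based window
#'   start indices.
#' @export
trial_features <- function(series, control = wg_control()) {
  wins <- sliding_windows(series, control$window_size, control$window_overlap)
  m <- t(vapply(wins, extract_features, numeric(23L),
                rate = series$rate,
                band_power_ratio = control$band_power_ratio))
  attr(m, "start") <- vapply(wins, attr, integer(1L), "start")
  m
}
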