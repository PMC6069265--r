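#' Construct a tri-axial acceleration series
#'
#' An `accel_series` holds a tri-axial wrist acceleration trace: a timestamp
#' vector in seconds and one acceleration value per axis and timestamp, in
#' m/s^2. When the samples lie on a uniform grid the sampling rate (Hz) is
#' attached; most of the pipeline (filtering, windowing, step detection)
#' requires a uniform series, which [resample_uniform()] produces.
#'
#' @param t Numeric vector of timestamps in seconds, monotone non-decreasing.
#' @param ax,ay,az Numeric vectors of per-axis acceleration in m/s^2, one
#'   value per timestamp.
#' @param rate Sampling rate in Hz, or `NULL` for a non-uniform series. If
#'   given, successive timestamp differences must equal `1/rate` within 1e-9.
#' @return An object of class `accel_series`: a list with elements `t`,
#'   `ax`, `ay`, `az` and `rate`.
#' @examples
#' s <- accel_series(t = (0:99) / 50, ax = sin(1:100), ay = rnorm(100),
#'                   az = rep(9.81, 100), rate = 50)
#' s
#' @export
accel_series <- function(t, ax, ay, az, rate = NULL) {
  n <- length(t)
  if (n < 2L)
    stop("an acceleration series needs at least 2 samples")
  if (length(ax) != n || length(ay) != n || length(az) != n)
    stop("t, ax, ay, az must have equal length")
  if (!all(is.finite(t)) || !all(is.finite(ax)) ||
      !all(is.finite(ay)) || !all(is.finite(az)))
    stop("non-finite values in acceleration series")
  if (any(diff(t) < 0))
    stop("timestamps must be monotone non-decreasing")
  if (!is.null(rate)) {
    if (rate <= 0) stop("rate must be positive")
    if (any(abs(diff(t) - 1 / rate) > 1e-9))
      stop("series declared uniform but timestamps are not on a 1/rate grid")
  }
  structure(list(t = as.numeric(t), ax = as.numeric(ax), ay = as.numeric(ay),
                 az = as.numeric(az), rate = rate),
            class = "accel_series")
}

#' @export
print.accel_series <- function(x, ...) {
  cat(sprintf("<accel_series> %d samples, %.3f s span, %s\n",
              length(x$t), x$t[length(x$t)] - x$t[1],
              if (is.null(x$rate)) "non-uniform"
              else sprintf("uniform at %g Hz", x$rate)))
  invisible(x)
}

#' @export
length.accel_series <- function(x) length(x$t)

#' Read / write an acceleration trace CSV
#'
#' The on-disk dialect is a plain UTF-8 CSV with a header row naming the
#' columns `t,ax,ay,az` (`time` or `timestamp` are accepted for `t`):
#' timestamps in seconds and accelerations in m/s^2. Duplicated timestamps
#' are accepted; the resampler handles them.
#'
#' @param path Path to the CSV file.
#' @return [read_accel_csv()] returns an `accel_series` (non-uniform; use
#'   [resample_uniform()] before filtering). [write_accel_csv()] returns
#'   `path` invisibly.
#' @export
read_accel_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  tcol <- match(TRUE, nm %in% c("t", "time", "timestamp"))
  if (is.na(tcol)) stop("missing timestamp column (t/time/timestamp) in ", path)
  for (ax in c("ax", "ay", "az"))
    if (!ax %in% nm) stop("missing column '", ax, "' in ", path)
  if (nrow(df) < 2L) stop("fewer than 2 data rows in ", path)
  cols <- c(tcol, match(c("ax", "ay", "az"), nm))
  for (j in cols) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric value in column '%s', row %d of %s",
                   names(df)[j], if (is.na(bad)) 1L else bad, path))
    }
  }
  accel_series(df[[cols[1]]], df[[cols[2]]], df[[cols[3]]], df[[cols[4]]])
}

#' @param series An `accel_series`.
#' @rdname read_accel_csv
#' @export
write_accel_csv <- function(series, path) {
  stopifnot(inherits(series, "accel_series"))
  utils::write.csv(data.frame(t = series$t, ax = series$ax, ay = series$ay,
                              az = series$az),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a series onto a uniform grid
#'
#' Linear interpolation of each axis onto a uniform grid running from the
#' first to the last timestamp. Linear interpolation is monotone, exact for
#' on-grid input and adequate for gait signals sampled well above the band
#' of interest.
#'
#' @param series An `accel_series`.
#' @param target_rate Target sampling rate in Hz.
#' @return A uniform `accel_series` at `target_rate`.
#' @export
resample_uniform <- function(series, target_rate) {
  stopifnot(inherits(series, "accel_series"))
  if (target_rate <= 0) stop("target_rate must be positive")
  t0 <- series$t[1]; t1 <- series$t[length(series$t)]
  span <- t1 - t0
  if (span < 2 / target_rate)
    stop("series too short to resample at ", target_rate, " Hz")
  mean_rate <- (length(series$t) - 1) / span
  if (target_rate > 2 * mean_rate)
    stop("target_rate ", target_rate,
         " Hz exceeds what the input density supports (mean input rate ",
         signif(mean_rate, 4), " Hz)")
  tout <- t0 + seq_len(floor(span * target_rate + 1e-9) + 1L) / target_rate -
    1 / target_rate
  interp <- function(v)
    stats::approx(series$t, v, xout = tout, ties = mean, rule = 2)$y
  accel_series(tout, interp(series$ax), interp(series$ay), interp(series$az),
               rate = target_rate)
}

## Digital Butterworth applied with reflection padding at both ends; the
## padding absorbs the start-up transient so that a constant maps to itself
## to machine precision and zero-phase filtering has no edge artefacts.
.pad_filter <- function(x, flt, zero_phase = TRUE, pad = 300L) {
  n <- length(x)
  p <- min(pad, n - 1L)
  xa <- c(2 * x[1] - rev(x[2:(p + 1L)]), x, 2 * x[n] - rev(x[(n - p):(n - 1L)]))
  y <- as.numeric(signal::filter(flt, xa))
  if (zero_phase)
    y <- rev(as.numeric(signal::filter(flt, rev(y))))
  y[(p + 1L):(p + n)]
}

#' Zero-phase Butterworth low-pass filter
#'
#' Filters each axis identically with a digital Butterworth low-pass. By
#' default the filter is applied forward and backward (zero-phase), so
#' peak/valley sample indices are not lagged; the effective attenuation is
#' then the squared single-pass magnitude response. Reflection padding keeps
#' edge transients out of the output, and length and timestamps are
#' unchanged.
#'
#' @param series A uniform `accel_series`.
#' @param cutoff Cut-off frequency in Hz (-3 dB point of a single pass);
#'   must be below the Nyquist frequency `rate/2`.
#' @param order Filter order (default 10).
#' @param zero_phase Apply forward-backward (default `TRUE`); `FALSE` gives a
#'   single causal pass, useful for inspecting the one-pass response.
#' @return The filtered `accel_series`.
#' @seealso [butter_gain()] for the analytic magnitude response.
#' @export
butterworth_lowpass <- function(series, cutoff, order = 10L,
                                zero_phase = TRUE) {
  stopifnot(inherits(series, "accel_series"))
  if (is.null(series$rate)) stop("series must be uniformly sampled; resample first")
  if (cutoff <= 0 || order < 1) stop("cutoff and order must be positive")
  if (cutoff >= series$rate / 2)
    stop("cutoff ", cutoff, " Hz is at or above the Nyquist frequency ",
         series$rate / 2, " Hz")
  flt <- signal::butter(order, 2 * cutoff / series$rate, type = "low")
  accel_series(series$t,
               .pad_filter(series$ax, flt, zero_phase),
               .pad_filter(series$ay, flt, zero_phase),
               .pad_filter(series$az, flt, zero_phase),
               rate = series$rate)
}

#' Analytic Butterworth amplitude response
#'
#' `|H(f)| = 1 / sqrt(1 + (f/fc)^(2 n))` for a single pass of an order-`n`
#' low-pass with cut-off `fc`; a zero-phase (forward-backward) application
#' has amplitude response `|H(f)|^2`.
#'
#' @param f Frequency in Hz (vectorised).
#' @param cutoff Cut-off frequency in Hz.
#' @param order Filter order.
#' @return Amplitude gain(s) in (0, 1].
#' @export
butter_gain <- function(f, cutoff, order = 10L) {
  1 / sqrt(1 + (f / cutoff)^(2 * order))
}

#' Remove the per-axis baseline
#'
#' Subtracts the per-axis mean, removing gravity and sensor offset so the
#' oscillatory gait component is signed and zero-centred; the adaptive
#' peak/valley thresholds require `min(a) < 0 < max(a)`. Idempotent.
#'
#' @param series An `accel_series`.
#' @return The zero-mean `accel_series`.
#' @export
remove_baseline <- function(series) {
  stopifnot(inherits(series, "accel_series"))
  accel_series(series$t,
               series$ax - mean(series$ax),
               series$ay - mean(series$ay),
               series$az - mean(series$az),
               rate = series$rate)
}

#' Standard preprocessing for a raw trace
#'
#' Resamples onto a uniform grid and applies the anti-noise low-pass: the
#' defaults (50 Hz grid, 15 Hz 10th-order zero-phase Butterworth) retain the
#' full band of human movement. Gravity is kept, so window features that use
#' per-axis means still see device orientation; step detection removes the
#' baseline separately.
#'
#' @param series A raw `accel_series`.
#' @param control A [wg_control()] list of pipeline settings.
#' @return A uniform, low-pass-filtered `accel_series`.
#' @export
preprocess_series <- function(series, control = wg_control()) {
  s <- if (is.null(series$rate) || series$rate != control$resample_rate)
    resample_uniform(series, control$resample_rate) else series
  butterworth_lowpass(s, control$prefilter_cutoff, control$prefilter_order)
}
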