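# Shared fixtures built in code.

# A uniform series with one sinusoid per axis.
tone_series <- function(freqs = c(2, 3, 5), amps = c(1, 1, 1), rate = 50,
                        dur = 10, offset = c(0, 0, 0)) {
  t <- seq(0, dur, by = 1 / rate)
  accel_series(t,
               offset[1] + amps[1] * sin(2 * pi * freqs[1] * t),
               offset[2] + amps[2] * sin(2 * pi * freqs[2] * t),
               offset[3] + amps[3] * sin(2 * pi * freqs[3] * t),
               rate = rate)
}

# A window matrix from per-axis vectors.
make_window <- function(x, y = x, z = x, rate = 50) {
  w <- cbind(ax = x, ay = y, az = z)
  attr(w, "rate") <- rate
  w
}

# Two well-separated Gaussian feature clusters in the 23-feature space.
separable_features <- function(n_per_class, labels, shift = 8, seed = 1) {
  stopifnot(length(labels) >= 2)
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_along(labels), function(i) {
    m <- matrix(stats::rnorm(n_per_class * 23, mean = i * shift, sd = 1),
                ncol = 23)
    m
  }))
  colnames(rows) <- wg_feature_names
  list(x = rows, y = rep(labels, each = n_per_class))
}

# RMS amplitude of a sinusoidal segment.
rms_amp <- function(x) sqrt(2 * mean(x^2))
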