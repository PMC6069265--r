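test_that("threshold initialisation follows the activity-specific rule", {
  sig <- c(2, -2, 1, -1)
  th_sw <- init_thresholds(sig, "swinging")
  expect_equal(th_sw$thp, 1.0)
  expect_equal(th_sw$thv, -1.4)
  th_tx <- init_thresholds(sig, "texting")
  expect_equal(th_tx$thp, 1.0)
  expect_equal(th_tx$thv, -1.0)
  expect_error(init_thresholds(c(1, 2, 3), "texting"), "oscillatory")
  expect_error(init_thresholds(-(1:3), "texting"), "oscillatory")
})

test_that("extrema detection counts cycles and derives the abnormal interval", {
  rate <- 50
  t <- seq(0, 10 - 1 / rate, by = 1 / rate)
  sig <- sin(2 * pi * 2 * t)            # 20 full cycles, interior extrema
  th <- init_thresholds(sig, "texting")
  ex <- find_extrema(sig, th, min_separation = 6)
  expect_equal(length(ex$peaks), 20L)
  expect_equal(length(ex$valleys), 20L)
  # valleys spaced one period apart: mu_d = 25 samples, abin = 32.5
  expect_equal(ex$mu_d, 25, tolerance = 0.1)
  expect_equal(ex$abin, 1.3 * ex$mu_d)
  # flat signal: empty sets, no error
  ex0 <- find_extrema(rep(0, 100), list(thp = 1, thv = -1), 5)
  expect_length(ex0$peaks, 0L)
  expect_length(ex0$valleys, 0L)
  expect_true(is.na(ex0$mu_d))
})

test_that("abnormal-interval arithmetic matches the definition", {
  # valleys at 10, 60, 110, 160 -> mu_d = 50, abin = 65
  sig <- rep(0.0, 200)
  sig[c(10, 60, 110, 160)] <- -2
  sig[c(35, 85, 135)] <- 2
  ex <- find_extrema(sig, list(thp = 1, thv = -1), 5)
  expect_equal(ex$valleys, c(10, 60, 110, 160))
  expect_equal(ex$mu_d, 50)
  expect_equal(ex$abin, 65)
})

test_that("minimum separation keeps the more extreme of close extrema", {
  sig <- rep(0, 100)
  sig[20] <- 1.5; sig[24] <- 2.0   # two peaks 4 samples apart
  sig[60] <- 2.0
  ex <- find_extrema(sig, list(thp = 1, thv = -1), min_separation = 6)
  expect_equal(ex$peaks, c(24, 60))
})

test_that("minimum correction recovers an attenuated valley", {
  rate <- 50
  t <- seq(0, 10 - 1 / rate, by = 1 / rate)
  sig <- -cos(2 * pi * 1 * t)          # valleys at t = 0, 1, 2, ... s
  # attenuate the valley at t = 5 s to 60% of the threshold
  i5 <- which.min(abs(t - 5))
  win <- abs(t - 5) <= 0.25
  sig[win] <- sig[win] * (1 - 0.7 * 0.5 * (1 + cos(pi * (t[win] - 5) / 0.25)))
  th <- init_thresholds(sig, "texting")
  ex <- find_extrema(sig, th, 10)
  expect_equal(length(ex$valleys), 8L)           # one of 9 interior missing
  mc <- minimum_correction(sig, ex, th)
  expect_equal(length(mc$valleys), 9L)           # recovered
  expect_equal(mc$log[["valleys_added"]], 1L)
  # recovered inside the attenuation window around t = 5 s
  expect_true(any(abs(mc$valleys - i5) <= 13))
  expect_true(all(diff(mc$valleys) > 0))
})

test_that("candidates below the noise floor or near gap edges are rejected", {
  # gap between valleys at 50 and 150 (mu_d from valleys ~50 apart elsewhere)
  sig <- rep(0, 300)
  sig[c(50, 150, 200, 250)] <- -2
  sig[c(60, 160, 210, 260)] <- 2      # peaks so thresholds exist
  # candidate in the gap but tiny: |a| = 0.05 -> noise
  sig[100] <- -0.05
  th <- list(thp = 1, thv = -1)
  ex <- find_extrema(sig, th, 5)
  mc <- minimum_correction(sig, ex, th)
  expect_false(100 %in% mc$valleys)
  expect_equal(mc$log[["gaps_uncorrected"]], 1L)

  # two valid candidates: the one with the largest |a| wins
  sig2 <- rep(0, 300)
  sig2[c(50, 150, 200, 250)] <- -2
  sig2[c(60, 160, 210, 260)] <- 2
  sig2[90] <- -0.5; sig2[110] <- -0.8
  ex2 <- find_extrema(sig2, th, 5)
  mc2 <- minimum_correction(sig2, ex2, th)
  expect_true(110 %in% mc2$valleys)
  expect_false(90 %in% mc2$valleys)
})

test_that("feedback rule uses a strict majority of reference intervals", {
  # build valleys 0..10 (11 valleys, 10 intervals); peaks configurable
  valleys <- seq(10, 210, by = 20)
  peak_in <- function(i, k) valleys[i] + k * 6  # k peaks inside interval i
  # claimed swinging, 6/10 intervals hold exactly 1 peak -> to_stage2
  peaks <- c(unlist(lapply(1:6, function(i) peak_in(i, 1))),
             unlist(lapply(7:10, function(i) valleys[i] + c(5, 12))))
  expect_identical(check_misclassification(valleys, peaks, "swinging"),
                   "to_stage2")
  # claimed texting, 6/10 intervals hold 2 peaks -> to_swing_detector
  peaks2 <- c(unlist(lapply(1:6, function(i) valleys[i] + c(5, 12))),
              unlist(lapply(7:10, function(i) peak_in(i, 1))))
  expect_identical(check_misclassification(valleys, peaks2, "texting"),
                   "to_swing_detector")
  # exactly 5/10 does not exceed the strict majority
  peaks3 <- c(unlist(lapply(1:5, function(i) valleys[i] + c(5, 12))),
              unlist(lapply(6:10, function(i) peak_in(i, 1))))
  expect_identical(check_misclassification(valleys, peaks3, "texting"),
                   "none")
  expect_identical(check_misclassification(valleys, peaks, "texting"),
                   "none")
})

test_that("maximum correction recovers missed peaks and prunes extras", {
  valleys <- c(1, 101, 201)
  sig <- rep(0, 300)
  sig[c(1, 101, 201)] <- -2
  sig[51] <- 0.6                       # sub-threshold local max, interval 1
  sig[c(130, 150, 170)] <- c(1.5, 2.0, 1.8)  # three peaks in interval 2
  peaks0 <- c(130, 150, 170)
  xc <- maximum_correction(sig, valleys, peaks0, "texting")
  expect_true(51 %in% xc$peaks)                  # recovered above valley level
  expect_identical(xc$peaks[xc$peaks > 101], 150)  # largest kept
  expect_equal(xc$log[["peaks_added"]], 1L)
  expect_equal(xc$log[["peaks_pruned"]], 2L)
  # swinging keeps the two largest
  xcs <- maximum_correction(sig, c(101, 201), peaks0, "swinging")
  expect_identical(xcs$peaks, c(150, 170))
  # interval already holding m peaks is untouched
  sig3 <- rep(0, 100); sig3[c(1, 99)] <- -2; sig3[50] <- 2
  xc3 <- maximum_correction(sig3, c(1, 99), 50, "texting")
  expect_identical(xc3$peaks, 50)
  expect_true(all(xc3$log == 0))
})

test_that("detection axis picks the gait-band axis and is zero-centred", {
  tr <- generate_trial(synthetic_trial_spec("calling", step_freq = 2,
                                            seed = 21))
  pre <- preprocess_series(tr$series)
  sig <- detection_signal(pre, "calling")
  expect_identical(attr(sig, "axis"), tr$truth$axis)
  expect_gt(max(sig), 0)
  expect_lt(min(sig), 0)
  # equal-power tie goes to the lowest axis index
  t <- (0:499) / 50
  s <- accel_series(t, sin(2 * pi * 2 * t), sin(2 * pi * 2 * t), 0 * t,
                    rate = 50)
  expect_identical(attr(detection_signal(s, "texting"), "axis"), "x")
  # override
  expect_identical(attr(detection_signal(s, "texting", axis = "y"), "axis"),
                   "y")
})

test_that("clean synthetic trials are recovered exactly", {
  for (a in c("pocket", "swinging")) {
    tr <- generate_trial(synthetic_trial_spec(a, step_freq = 1.6, seed = 31))
    det <- detect_steps(preprocess_series(tr$series), a)
    expect_identical(det$feedback, "none")
    expect_length(det$steps, tr$truth$n_steps)
    # valleys strictly increasing, peaks inside intervals
    expect_true(all(diff(det$valleys) > 0))
    for (st in det$steps) {
      expect_lt(st$valley_before, st$peak)
      expect_lt(st$peak, st$valley_after)
      expect_gt(st$duration, 0)
    }
  }
})

test_that("step events carry consistent slices and durations", {
  tr <- generate_trial(synthetic_trial_spec("texting", n_steps = 12,
                                            seed = 8))
  det <- detect_steps(preprocess_series(tr$series), "texting")
  st <- det$steps[[3]]
  expect_equal(nrow(st$slice), st$valley_after - st$valley_before)
  expect_equal(length(st$det), nrow(st$slice))
  expect_equal(st$duration,
               (st$valley_after - st$valley_before) / det$rate)
})

test_that("a mislabeled trial is rerouted once and then resolved", {
  sw <- generate_trial(synthetic_trial_spec("swinging", seed = 51))
  pre <- preprocess_series(sw$series)
  det <- detect_steps(pre, "texting")
  expect_identical(det$feedback, "to_swing_detector")
  expect_length(det$steps, 0L)       # rerouted trials carry no steps
  det2 <- detect_steps(pre, "swinging")
  expect_identical(det2$feedback, "none")
  expect_length(det2$steps, sw$truth$n_steps)

  tx <- generate_trial(synthetic_trial_spec("pocket", seed = 52))
  pre2 <- preprocess_series(tx$series)
  detx <- detect_steps(pre2, "swinging")
  expect_identical(detx$feedback, "to_stage2")
  detx2 <- detect_steps(pre2, "pocket")
  expect_length(detx2$steps, tx$truth$n_steps)
})

test_that("too-short trials raise the documented error", {
  t <- (0:199) / 50
  s <- accel_series(t, 0.05 * sin(2 * pi * 0.2 * t) + rep(c(1, -1), 100) * 0.001,
                    rnorm(200, 0, 0.001), rnorm(200, 0, 0.001), rate = 50)
  expect_error(detect_steps(s, "texting"), "too short|oscillatory")
})

test_that("corrections restore artifact-degraded trials", {
  spec <- synthetic_trial_spec("suitcase", step_freq = 1.8, seed = 61,
                               artifact_rates = c(valley_attenuation = 0.1,
                                                  peak_attenuation = 0.05))
  tr <- generate_trial(spec)
  pre <- preprocess_series(tr$series)
  with_c <- detect_steps(pre, "suitcase", corrections = TRUE)
  no_c <- detect_steps(pre, "suitcase", corrections = FALSE)
  expect_length(with_c$steps, tr$truth$n_steps)
  expect_true(sum(with_c$corrections_log) > 0)
  expect_lt(length(no_c$steps), tr$truth$n_steps)
})

test_that("spurious super-threshold bumps are pruned by maximum correction", {
  spec <- synthetic_trial_spec("texting", step_freq = 1.6, seed = 71,
                               artifact_rates = c(spurious_extrema = 0.2))
  tr <- generate_trial(spec)
  det <- detect_steps(preprocess_series(tr$series), "texting")
  expect_length(det$steps, tr$truth$n_steps)
})
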