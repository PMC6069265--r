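test_that("trial specs validate the walking-band and step constraints", {
  expect_error(synthetic_trial_spec("texting", step_freq = 0.5), "1.2")
  expect_error(synthetic_trial_spec("texting", n_steps = 2), ">= 4")
  expect_error(synthetic_trial_spec("swinging", n_steps = 9), "even")
  expect_error(synthetic_trial_spec("texting", amplitude = -1), "positive")
  expect_error(synthetic_trial_spec("texting",
                                    artifact_rates = c(peak_attenuation = 2)),
               "0, 1")
  expect_error(synthetic_trial_spec("running"), "activity")
})

test_that("generated trials honour their ground truth by construction", {
  sp <- synthetic_trial_spec("texting", n_steps = 20, noise_sd = 0, seed = 5)
  tr <- generate_trial(sp)
  expect_length(tr$truth$step_times, 20L)
  expect_length(tr$truth$step_lengths, 20L)
  expect_equal(tr$truth$total_distance, sum(tr$truth$step_lengths))
  expect_equal(tr$truth$total_distance, 20 * sp$mean_step_length,
               tolerance = 1e-9)
  # detection axis carries exactly n_steps super-threshold maxima
  det <- detect_steps(preprocess_series(tr$series), "texting")
  expect_length(det$steps, 20L)

  sw <- generate_trial(synthetic_trial_spec("swinging", n_steps = 20,
                                            noise_sd = 0, seed = 6))
  expect_length(sw$truth$valley_times, 11L)  # 10 arm cycles
  dsw <- detect_steps(preprocess_series(sw$series), "swinging")
  expect_length(dsw$steps, 20L)
})

test_that("generation is bit-deterministic in the seed", {
  sp <- synthetic_trial_spec("calling", seed = 77)
  t1 <- generate_trial(sp)
  t2 <- generate_trial(sp)
  expect_identical(t1$series$ax, t2$series$ax)
  expect_identical(t1$truth$step_lengths, t2$truth$step_lengths)
  t3 <- generate_trial(synthetic_trial_spec("calling", seed = 78))
  expect_false(identical(t1$series$ax, t3$series$ax))
})

test_that("the non-swing spectrum peaks at the step frequency", {
  tr <- generate_trial(synthetic_trial_spec("suitcase", step_freq = 2,
                                            seed = 9))
  pre <- preprocess_series(tr$series)
  x <- pre[[paste0("a", tr$truth$axis)]]
  pg <- wristgait:::.periodogram(x - mean(x), pre$rate)
  fmax <- pg$freq[which.max(pg$S)]
  bin <- pre$rate / length(x)
  expect_lt(abs(fmax - 2), bin + 1e-9)
})

test_that("artifact injection is seeded, counted and truth-preserving", {
  sp <- synthetic_trial_spec("texting", n_steps = 21, seed = 12)  # 20 interior valleys
  tr <- generate_trial(sp)
  inj <- inject_artifacts(tr, c(valley_attenuation = 0.1), seed = 3)
  expect_identical(inj$truth, tr$truth)
  col <- paste0("a", tr$truth$axis)
  # exactly 2 of the 20 interior valleys attenuated
  changed <- which(abs(inj$series[[col]] - tr$series[[col]]) > 1e-12)
  expect_gt(length(changed), 0)
  vt <- tr$truth$valley_times[-c(1, length(tr$truth$valley_times))]
  near_valley <- vapply(vt, function(tv)
    any(abs(tr$series$t[changed] - tv) < 0.3 / sp$step_freq), logical(1))
  expect_equal(sum(near_valley), 2L)
  # identity at zero rates
  expect_identical(inject_artifacts(tr, c(valley_attenuation = 0)), tr)
  # attenuated valleys stay above the noise floor
  pre <- preprocess_series(inj$series)
  sig <- detection_signal(pre, "texting")
  for (tv in vt) {
    i <- which(abs(pre$t - tv) < 0.02)
    expect_gt(max(abs(sig[i])), 0.1)
  }
  # reproducible
  inj2 <- inject_artifacts(tr, c(valley_attenuation = 0.1), seed = 3)
  expect_identical(inj$series[[col]], inj2$series[[col]])
})

test_that("dataset generation is balanced, 20 m, and bit-reproducible", {
  ds <- generate_dataset(n_subjects = 2, trials_per_activity = 2,
                         speed_levels = c(1.4, 1.8, 2.2), seed = 4)
  expect_equal(nrow(ds$meta), 60L)     # 2 x 5 x 3 x 2
  expect_length(ds$trials, 60L)
  expect_true(all(ds$meta$true_distance_m == 20))
  expect_true(all(table(ds$meta$activity) == 12L))
  expect_true(all(ds$meta$height_m >= 1.5 & ds$meta$height_m <= 1.9))
  for (i in c(1L, 30L))
    expect_equal(ds$trials[[i]]$truth$total_distance, 20, tolerance = 1e-9)
  ds2 <- generate_dataset(n_subjects = 2, trials_per_activity = 2,
                          speed_levels = c(1.4, 1.8, 2.2), seed = 4)
  expect_identical(ds$trials[[17]]$series$ay, ds2$trials[[17]]$series$ay)
  expect_identical(ds$meta, ds2$meta)
})

test_that("raw traces are 62.5 Hz with mild timestamp jitter", {
  tr <- generate_trial(synthetic_trial_spec("pocket", seed = 2))
  dt <- diff(tr$series$t)
  expect_true(is.null(tr$series$rate))
  expect_equal(median(dt), 1 / 62.5, tolerance = 0.2)
  expect_true(all(dt >= 0))
  expect_gt(sd(dt), 0)   # jitter present
})
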