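# Independent oracle: global polynomial weighted least squares by explicit
# normal equations, beta = (V' W V)^-1 (V' W K).
wls_oracle <- function(v, k, degree, w = rep(1, length(v))) {
  V <- outer(v, 0:degree, `^`)
  solve(t(V) %*% (w * V), t(V) %*% (w * k))
}

test_that("step velocity integrates a sinusoidal slice to the closed form", {
  # a(t) = sin(2 pi t / T) over [0, T): mean velocity magnitude = T / (2 pi)
  rate <- 200
  T <- 0.5
  tt <- seq(0, T - 1 / rate, by = 1 / rate)
  slice <- cbind(sin(2 * pi * tt / T), 0 * tt, 0 * tt)
  st <- list(slice = slice, rate = rate)
  expect_equal(step_velocity(st), T / (2 * pi), tolerance = 0.01)
  # zero acceleration -> zero velocity; scaling is homogeneous
  expect_equal(step_velocity(list(slice = slice * 0, rate = rate)), 0)
  expect_equal(step_velocity(list(slice = slice * 3, rate = rate)),
               3 * step_velocity(st), tolerance = 1e-12)
})

test_that("training K pairs invert the step-length equations", {
  mk_step <- function(det, dur, rate = 50) {
    n <- length(det)
    list(slice = cbind(det, rep(0, n), rep(0, n)), det = det,
         duration = dur, rate = rate)
  }
  # weinberg: 20 m over 25 steps, A_max - A_min = 16 -> L = 0.8, K = 0.2
  det <- c(8, 0, -8, 0)
  steps <- replicate(25, mk_step(det, 0.5), simplify = FALSE)
  kw <- compute_training_k(steps, 20, "weinberg", height = 1.7)
  expect_equal(kw$k, rep(0.8 / 16^0.25, 25), tolerance = 1e-9)
  # kim: all |A| = 8 -> M = 2, K = L / 2
  det8 <- c(8, -8, 8, -8)
  steps8 <- replicate(25, mk_step(det8, 0.5), simplify = FALSE)
  kk <- compute_training_k(steps8, 20, "kim", height = 1.7)
  expect_equal(kk$k, rep(0.8 / 2, 25), tolerance = 1e-9)
  # tian: h = 1.75, fs = 2 -> M = 3.5
  steps_t <- replicate(25, mk_step(det, 0.5), simplify = FALSE)
  kt <- compute_training_k(steps_t, 20, "tian", height = 1.75)
  expect_equal(kt$k, rep(0.8 / 3.5, 25), tolerance = 1e-9)
})

test_that("step-length equations match closed-form examples", {
  f <- list(a_max = 8, a_min = -8, a_mean = 8, fs = 2, h = 1.75)
  expect_equal(step_length("weinberg", f, K = 1), 2, tolerance = 1e-9)
  expect_equal(step_length("kim", f, K = 0.5), 1, tolerance = 1e-9)
  expect_equal(step_length("tian", f, K = 0.4), 1.4, tolerance = 1e-9)
  expect_error(step_length("weinberg",
                           list(a_max = -1, a_min = 1, a_mean = 1,
                                fs = 1, h = 1), K = 1), "a_max")
  expect_error(step_length("tian", f, K = -1), "positive")
})

test_that("trial distance is the plain sum", {
  expect_equal(trial_distance(c(0.7, 0.7, 0.6)), 2)
  expect_equal(trial_distance(1.23), 1.23)
  set.seed(1)
  x <- runif(20)
  expect_equal(trial_distance(sample(x)), trial_distance(x))
  expect_error(trial_distance(numeric(0)), "no step")
})

test_that("estimator selection maps activities as published", {
  expect_identical(select_estimator("texting"), "tian")
  expect_identical(select_estimator("calling"), "tian")
  expect_identical(select_estimator("suitcase"), "tian")
  expect_identical(select_estimator("pocket"), "kim")
  expect_identical(select_estimator("swinging"), "kim")
  ctl <- wg_control(estimator_map = c(texting = "weinberg", calling = "tian",
                                      suitcase = "tian", pocket = "kim",
                                      swinging = "kim"))
  expect_identical(select_estimator("texting", ctl), "weinberg")
})

test_that("noiseless polynomial data is recovered exactly", {
  set.seed(5)
  v <- runif(50, 0.5, 2)
  k <- 0.3 + 0.1 * v
  m <- fit_k_model(v, k, "tian", degree = 1, bandwidth = 1e6)
  expect_equal(as.numeric(predict_k(m, v)), k, tolerance = 1e-8)
  # constant K, any degree
  m0 <- fit_k_model(v, rep(0.42, 50), "kim", degree = 4)
  expect_equal(as.numeric(predict_k(m0, c(0.7, 1.5))), c(0.42, 0.42),
               tolerance = 1e-8)
  # degree 0 = locally weighted mean
  m2 <- fit_k_model(v, k, "tian", degree = 0, bandwidth = 0.3)
  w <- exp(-0.5 * ((v - 1) / 0.3)^2)
  expect_equal(as.numeric(predict_k(m2, 1)), sum(w * k) / sum(w),
               tolerance = 1e-8)
  # determinism under duplication of the training set
  m3 <- fit_k_model(c(v, v), c(k, k), "tian", degree = 1, bandwidth = 1e6)
  expect_equal(predict_k(m3, v), predict_k(m, v), tolerance = 1e-8)
})

test_that("infinite-bandwidth limit equals global WLS by normal equations", {
  set.seed(11)
  for (rep in 1:10) {
    n <- 100
    v <- runif(n, 0.3, 2.5)
    k <- 0.5 + 0.2 * v - 0.05 * v^2 + rnorm(n, 0, 0.05)
    deg <- sample(0:4, 1)
    m <- fit_k_model(v, k, "kim", degree = deg, bandwidth = 1e7)
    beta <- wls_oracle(v, k, deg)
    q <- runif(5, min(v), max(v))
    expect_equal(as.numeric(predict_k(m, q)),
                 as.numeric(outer(q, 0:deg, `^`) %*% beta),
                 tolerance = 1e-6)
  }
})

test_that("queries outside the training range are clamped and flagged", {
  set.seed(2)
  v <- runif(40, 1, 2)
  k <- 0.2 + 0.1 * v
  m <- fit_k_model(v, k, "tian", degree = 1, bandwidth = 1e6)
  p <- predict_k(m, c(0.5, 1.5, 3))
  expect_identical(attr(p, "extrapolated"), c(TRUE, FALSE, TRUE))
  expect_equal(as.numeric(p[1]), as.numeric(predict_k(m, min(v))),
               tolerance = 1e-10)
  expect_equal(as.numeric(p[3]), as.numeric(predict_k(m, max(v))),
               tolerance = 1e-10)
})

test_that("degree-4 polynomial plus noise is recovered to near noise level", {
  set.seed(97)
  n <- 500
  sigma <- 0.03
  v <- runif(n, 0.4, 2.0)
  q <- function(x) 0.4 + 0.15 * x - 0.1 * x^2 + 0.04 * x^3 - 0.005 * x^4
  k <- q(v) + rnorm(n, 0, sigma)
  m <- fit_k_model(v, k, "tian", degree = 4)
  grid <- seq(0.45, 1.95, length.out = 100)
  rmse <- sqrt(mean((as.numeric(predict_k(m, grid)) - q(grid))^2))
  expect_lte(rmse, 1.2 * sigma)
})

test_that("rank-deficient local systems fall back to a ridge solution", {
  v <- rep(c(1, 2, 3, 4, 5), each = 2)    # 5 distinct values, degree 4
  k <- 0.1 * v
  m <- fit_k_model(v, k, "tian", degree = 4, bandwidth = 0.05)
  # with a tiny bandwidth only one support point carries weight: the
  # local system is numerically rank deficient yet prediction stays finite
  p <- predict_k(m, 2.5)
  expect_true(is.finite(p))
})
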