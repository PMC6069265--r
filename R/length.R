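#' Per-step mean-velocity magnitude
#'
#' The velocity feature driving the K-factor model. Each axis of the step's
#' tri-axial slice is mean-removed (the standard pedestrian drift guard:
#' zero net velocity change over a step) and integrated by the trapezoid
#' rule from zero initial velocity; the feature is the Euclidean norm of the
#' three per-axis mean velocities.
#'
#' @param step One step event from [detect_steps()] (needs `slice` and
#'   `rate`).
#' @return Non-negative scalar, m/s.
#' @export
step_velocity <- function(step) {
  a <- step$slice
  n <- nrow(a)
  if (n < 2L) return(0)
  vm <- vapply(1:3, function(j) {
    x <- a[, j] - mean(a[, j])
    v <- c(0, cumsum((x[-1L] + x[-n]) / 2)) / step$rate
    mean(v)
  }, numeric(1))
  sqrt(sum(vm^2))
}

## Per-step features consumed by the three step-length kernels. a_max/a_min
## come from the 5 Hz detection-axis slice; fs is the inverse step duration.
.step_features <- function(step, height) {
  list(v_bar = step_velocity(step),
       a_max = max(step$det), a_min = min(step$det),
       a_mean = mean(abs(step$det)),
       fs = 1 / step$duration, h = height)
}

## The method-specific magnitude each K multiplies.
.method_kernel <- function(method, f) {
  switch(method,
         weinberg = {
           if (f$a_max <= f$a_min) stop("a_max must exceed a_min")
           (f$a_max - f$a_min)^(1 / 4)
         },
         kim = f$a_mean^(1 / 3),
         tian = f$h * f$fs,
         stop("unknown method: ", method))
}

#' Training pairs for the K-factor model
#'
#' Inverts the chosen step-length equation on a ground-truth trial: each
#' step's true length is taken as the trial distance divided by the step
#' count (only trial totals are observable), and `K_i = L_i / M_i` with
#' `M_i` the method kernel -- `(A_max - A_min)^(1/4)` (Weinberg),
#' `(mean |A_k|)^(1/3)` (Kim) or `h * f_s` (Tian). Steps with a zero kernel
#' are skipped with a warning.
#'
#' @param steps List of step events (or a `step_detection` object).
#' @param true_distance Trial ground-truth distance in metres (> 0).
#' @param method `"weinberg"`, `"kim"` or `"tian"`.
#' @param height Subject height in metres.
#' @return `data.frame` with columns `v_bar` and `k`.
#' @export
compute_training_k <- function(steps, true_distance, method, height) {
  if (inherits(steps, "step_detection")) steps <- steps$steps
  if (!length(steps)) stop("no steps")
  if (true_distance <= 0) stop("true_distance must be positive")
  L <- true_distance / length(steps)
  rows <- lapply(steps, function(s) {
    f <- .step_features(s, height)
    M <- .method_kernel(method, f)
    if (M == 0) return(NULL)
    data.frame(v_bar = f$v_bar, k = L / M)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped) warning(skipped, " step(s) with zero kernel skipped")
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("all steps had zero kernel")
  out
}

#' Fit the locally weighted polynomial K-factor model
#'
#' The K-factor is modelled as a degree-`p` polynomial in the per-step
#' mean-velocity magnitude, fitted locally: for each query the polynomial
#' coefficients solve the weighted least-squares problem
#' `min_beta (K - V beta)' W (K - V beta)` with `V` the Vandermonde matrix
#' of the training velocities and `W` diagonal Gaussian weights centred at
#' the query. The model is lazy -- it stores the training pairs and
#' hyperparameters; coefficients are solved per query by [predict_k()].
#'
#' @param v_bar Training step velocities (m/s).
#' @param k Training K-factors.
#' @param method Which step-length equation the K belongs to.
#' @param degree Polynomial degree `p` (default 4).
#' @param bandwidth Gaussian kernel bandwidth in v-bar units; default
#'   (`NULL`) is Silverman's rule of thumb on the training velocities.
#' @return An object of class `klocpoly`.
#' @export
fit_k_model <- function(v_bar, k, method = c("weinberg", "kim", "tian"),
                        degree = 4L, bandwidth = NULL) {
  method <- match.arg(method)
  stopifnot(length(v_bar) == length(k), all(is.finite(v_bar)),
            all(is.finite(k)))
  degree <- as.integer(degree)
  if (degree < 0) stop("degree must be >= 0")
  if (length(unique(v_bar)) < degree + 1L)
    stop("need at least degree + 1 distinct v_bar values")
  if (is.null(bandwidth)) {
    bandwidth <- stats::bw.nrd0(v_bar)
    if (!is.finite(bandwidth) || bandwidth <= 0)
      bandwidth <- max(stats::sd(v_bar), diff(range(v_bar)) / 10, 1e-3)
  }
  if (bandwidth <= 0) stop("bandwidth must be positive")
  structure(list(v = as.numeric(v_bar), k = as.numeric(k), method = method,
                 degree = degree, bandwidth = bandwidth,
                 n = length(v_bar)),
            class = "klocpoly")
}

#' @export
print.klocpoly <- function(x, ...) {
  cat(sprintf(paste0("<klocpoly> %s K-factor: degree %d, bandwidth %.4g, ",
                     "%d training steps\n  v_bar range [%.3f, %.3f] m/s, ",
                     "K range [%.4f, %.4f]\n"),
              x$method, x$degree, x$bandwidth, x$n, min(x$v), max(x$v),
              min(x$k), max(x$k)))
  invisible(x)
}

## One local weighted least-squares solve, QR-based with a small ridge
## fallback on rank deficiency. If the query lands in a sparse region the
## bandwidth is widened until the effective local sample size supports the
## polynomial degree (a k-nearest-neighbour-style floor); without it a
## high-degree local fit in a data gap can oscillate wildly.
.local_beta <- function(v, k, x0, degree, bandwidth) {
  w <- exp(-0.5 * ((v - x0) / bandwidth)^2)
  need <- 2 * (degree + 1)
  tries <- 0L
  while (sum(w) < need && tries < 30L) {
    bandwidth <- 1.5 * bandwidth
    w <- exp(-0.5 * ((v - x0) / bandwidth)^2)
    tries <- tries + 1L
  }
  w <- pmax(w, 1e-300)
  V <- outer(v, 0:degree, `^`)
  fit <- stats::lm.wfit(V, k, w)
  beta <- fit$coefficients
  if (anyNA(beta) || fit$rank < degree + 1L) {
    A <- crossprod(V * w, V) + diag(1e-8, degree + 1L)
    beta <- solve(A, crossprod(V * w, k))
  }
  as.numeric(beta)
}

#' Predict the K-factor at query velocities
#'
#' Solves the local weighted least-squares system at each query and
#' evaluates the local polynomial there. Queries outside the training
#' velocity range are clamped to the nearest edge (a local polynomial must
#' not be extrapolated); the returned vector carries a logical
#' `extrapolated` attribute flagging them.
#'
#' @param model A `klocpoly` from [fit_k_model()].
#' @param v_bar Query velocities (vectorised).
#' @return Numeric vector of K-factors.
#' @export
predict_k <- function(model, v_bar) {
  stopifnot(inherits(model, "klocpoly"))
  lo <- min(model$v); hi <- max(model$v)
  out <- vapply(v_bar, function(x0) {
    xq <- min(max(x0, lo), hi)
    beta <- .local_beta(model$v, model$k, xq, model$degree, model$bandwidth)
    p <- sum(xq^(0:model$degree) * beta)
    ## K is a physical scale factor; a non-positive local fit signals an
    ## unstable solve, so fall back to the locally weighted mean there
    if (!is.finite(p) || (p <= 0 && all(model$k > 0))) {
      w <- exp(-0.5 * ((model$v - xq) / model$bandwidth)^2)
      p <- sum(w * model$k) / sum(w)
    }
    p
  }, numeric(1))
  attr(out, "extrapolated") <- v_bar < lo | v_bar > hi
  out
}

#' @export
predict.klocpoly <- function(object, newdata, ...) predict_k(object, newdata)

#' Step length from features and K-factor
#'
#' The three adapted step-length equations: Weinberg
#' `K * (A_max - A_min)^(1/4)`, Kim `K * (mean |A_k|)^(1/3)` and Tian
#' `K * h * f_s`.
#'
#' @param method `"weinberg"`, `"kim"` or `"tian"`.
#' @param features Per-step feature list with `a_max`, `a_min`, `a_mean`,
#'   `fs`, `h` (see [compute_training_k()] internals), or a step event plus
#'   `height`.
#' @param K The step's K-factor (> 0).
#' @param height Subject height (m), used when `features` is a step event.
#' @return Step length in metres.
#' @export
step_length <- function(method, features, K, height = NULL) {
  if (!is.null(features$slice)) features <- .step_features(features, height)
  if (K <= 0) stop("K must be positive")
  K * .method_kernel(method, features)
}

#' Total trial distance
#'
#' Sum of the per-step lengths.
#' @param step_lengths Numeric vector of step lengths (m), non-empty.
#' @return Distance in metres.
#' @export
trial_distance <- function(step_lengths) {
  if (!length(step_lengths)) stop("no step lengths")
  sum(step_lengths)
}

#' Which step-length estimator serves an activity
#'
#' The per-activity choice that maximises accuracy: the non-parametric Tian
#' estimator for texting, calling and suitcase carrying; the non-parametric
#' Kim estimator for hand-in-pocket and swinging.
#'
#' @param activity Activity label.
#' @param control A [wg_control()] list (the map is configurable there).
#' @return `"weinberg"`, `"kim"` or `"tian"`.
#' @export
select_estimator <- function(activity, control = wg_control()) {
  .check_activity(activity)
  unname(control$estimator_map[[activity]])
}

#' Estimate the walked distance of a detected trial
#'
#' Applies a fitted K-factor model step by step and sums the lengths.
#'
#' @param detection A `step_detection` with at least one step.
#' @param model A `klocpoly` fitted for the same method.
#' @param height Subject height in metres.
#' @return List with `distance` (m) and `steps` (`data.frame`: `v_bar`,
#'   `K`, `length`).
#' @export
estimate_distance <- function(detection, model, height) {
  stopifnot(inherits(detection, "step_detection"), inherits(model, "klocpoly"))
  if (!length(detection$steps)) stop("detection contains no steps")
  feats <- lapply(detection$steps, .step_features, height = height)
  v <- vapply(feats, `[[`, numeric(1), "v_bar")
  K <- as.numeric(predict_k(model, v))
  len <- vapply(seq_along(feats), function(i)
    K[i] * .method_kernel(model$method, feats[[i]]), numeric(1))
  list(distance = trial_distance(len),
       steps = data.frame(v_bar = v, K = K, length = len))
}
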