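---
title: "Walking distance from a wrist-worn accelerometer: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Walking distance from a wrist-worn accelerometer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristgait)
```

## The problem

A single wrist-worn tri-axial accelerometer observes walking through the
arm, and the arm does different things while its owner walks: it holds a
phone still (texting, calling), hangs in a pocket, drags a suitcase, or
swings freely. The observable gait signature differs accordingly — the four
*centre-of-mass* activities show the torso's vertical oscillation with one
acceleration peak between consecutive valleys per step, while arm swinging
superimposes the arm's pendular motion and shows **two** peaks per
valley-to-valley interval (one arm cycle spans two steps). A step counter
or distance estimator that ignores this structure fails in characteristic
ways, which is why the pipeline is hierarchical:

1. **Activity recognition** — two SVM stages on 23 windowed features:
   swing vs the rest, then the four centre-of-mass activities.
2. **Robust step detection** — activity-conditioned adaptive thresholds on
   the 5 Hz-filtered detection axis, with three safety nets: *minimum
   correction* (re-detect valleys inside abnormally wide valley gaps with a
   relaxed threshold), *misclassification feedback* (if the
   peaks-per-interval statistic contradicts the claimed activity, reroute
   the trial to the other classifier/detector), and *maximum correction*
   (recover or prune peaks per reference interval).
3. **Step-length estimation** — the Weinberg, Kim and Tian step-length
   equations with their scale constant K modelled non-parametrically, as a
   locally weighted degree-p polynomial in the per-step mean-velocity
   magnitude; trial distance is the sum of step lengths.

## Preprocessing

Raw traces (nominally 62.5 Hz, jittered timestamps) are linearly
interpolated onto a uniform 50 Hz grid and low-pass filtered at 15 Hz with
a 10th-order Butterworth filter: human movement lives below 15 Hz, and
linear interpolation is monotone and exact for band-limited content this
far below Nyquist. Filtering is applied **zero-phase** (forward and
backward, with reflection padding): the analysis is offline, and zero lag
matters because peak and valley *sample indices* downstream define step
boundaries. The price is that the effective amplitude response is the
square of the single-pass response; `butter_gain()` exposes the analytic
curve, and the package contracts are: unity DC gain to 1e-9, −3 dB at the
cutoff for a single pass, and a stop-band residual orders of magnitude
under 1%.

Gravity handling is deliberately split. Window features keep gravity: the
per-axis means encode device orientation, which is exactly what separates
texting from pocket from suitcase in stage 2. Step detection removes the
per-axis mean per trial (`remove_baseline()`): the adaptive thresholds
`thp = 0.5·max(a)`, `thv = 0.5·min(a)` (0.7 for the swing valley) assume a
signed, zero-centred signal. Mean subtraction is the simplest transform
with that property; nothing in the method needs a finer gravity estimate.

## Features and classifiers

Each 100-sample window (2 s, 50% overlap) yields 23 features: average
spectral energy AE (1), signal magnitude area SMA (1), intensity of
movement per axis (3), mean and population standard deviation per axis
(3+3), band power in 0–0.5 / 0.5–1 / 1–5 Hz per axis (9), and peak power —
the sum of the five dominant periodogram ordinates — per axis (3). This
per-axis expansion is the unique one consistent with the count of 23.
Band powers integrate the raw periodogram of the mean-removed window
trapezoid-style between the band edges; a config switch
(`wg_control(band_power_ratio = TRUE)`) turns them into ratios of total
power for users who read "power ratio" literally — absolute power is the
default because the defining equation is an absolute integral.

Stage 1 uses the intensity/spectral subset (SMA, IM, AE, band and peak
powers); stage 2 swaps SMA/IM for the orientation-sensitive means and
standard deviations. Both stages are radial-kernel SVMs (`e1071`) with
features z-standardised by training-set statistics stored in the stage
object; the kernel and cost (default 1) are configurable but deliberately
unremarkable — on this problem the feature design, not the classifier,
carries the separation. Trials are labelled by majority vote over their
windows; stage-1 ties go to the centre-of-mass group (the larger prior,
4 of 5 activities), stage-2 ties break lexicographically.

## Step detection

The detection axis is chosen as the axis with maximal 1–3 Hz periodogram
power — the vertical component migrates between device axes across
activities, and the gait band identifies it without per-activity tables (a
config override exists). The axis is refiltered at 5 Hz (order 4; only the
cutoff is fixed by the method, and a gentler roll-off is numerically
comfortable while the extremum structure needs no more).

Initial extrema are local maxima above `thp` and minima below `thv`, with
extrema of the same kind closer than a minimum spacing (derived from the
dominant gait-band frequency) pruned to the more extreme one. The spacing
is asymmetric by design: a quarter of the expected step period for peaks
but 0.4 of it for valleys. Valleys deserve the stricter rule because they
define the reference intervals and the correction machinery can *add* but
never *remove* a valley — a noise-split twin valley would fabricate an
interval that maximum correction then dutifully fills with a step — whereas
surplus peaks are pruned per interval anyway. True valleys sit a full step
period apart (two for swinging), so the 0.4 spacing has a 2.5x margin.
The mean valley spacing `mu_d` defines the abnormal interval
`Ab_in = 1.3·mu_d`; any wider valley gap is assumed to hide a missed
valley. Inside such a gap the valley threshold is relaxed geometrically
toward zero (`thv ← 0.8·thv`, at most 10 iterations) — toward zero is the
only direction that admits *shallower* valleys, which is what an
attenuated signal produces. A candidate must clear the 0.1 m/s² noise
floor and sit at least `mu_d/4` from both gap endpoints; among several,
the largest |a| wins. Gaps that stay empty are logged, not invented.

The feedback check runs between the corrections: counting peaks strictly
inside each reference interval, a claimed swing trial whose one-peak
intervals strictly exceed half is sent back to stage 2, and a claimed
centre-of-mass trial whose two-peak intervals strictly exceed half is sent
to the swing detector. One reroute per trial is allowed; a second,
conflicting feedback keeps the second detector's result and warns —
without the bound the two detectors could ping-pong forever on a
pathological trial.

Maximum correction then enforces the per-interval peak count m (2 for
swing, 1 otherwise): deficits trigger re-detection with the threshold
lowered to the larger of the two bounding valleys' values (the noise floor
still applies), surpluses keep the m largest peaks. Every corrected peak
is a step. Swing intervals are split at the midpoint between their two
peaks so each step gets its own duration — the Tian equation needs a
per-step frequency.

## Step length

The per-step velocity feature integrates the mean-removed tri-axial slice
(trapezoid rule, zero initial velocity) and takes the norm of the three
per-axis mean velocities. Mean removal is the standard pedestrian
zero-velocity-update assumption: over one step the wrist returns to its
cyclic trajectory, so net velocity change is drift, not signal. Of the two
readings of "magnitude of the average velocities on three axes", the norm
of the per-axis means is implemented (the literal one); the alternative —
the time-mean of the speed — is monotonically related on this signal
family.

Training pairs invert the chosen step-length equation on ground-truth
trials: per-step truth does not exist (only trial totals), so each step of
a training trial is assigned `L = D_true / n_steps`. The K-factor is then
`K_i = L_i / M_i`, with kernels `M` = `(A_max − A_min)^(1/4)` (Weinberg),
`(mean |A_k|)^(1/3)` (Kim, absolute values so the cube root stays real on
zero-centred signals) or `h·f_s` (Tian). The model `fit_k_model()` is lazy:
it stores the pairs and hyperparameters; `predict_k()` solves the weighted
least-squares system per query with Gaussian weights centred there
(degree 4 by default; the bandwidth defaults to Silverman's rule of thumb
on the training velocities — the method fixes a Gaussian weight function
but no bandwidth, and Silverman is the standard data-driven default). The local solve uses a QR factorisation (`lm.wfit`), not the
explicit normal-equation inverse, with a 1e-8 ridge fallback on rank
deficiency. Queries outside the training range are clamped to the nearest
edge and flagged: extrapolating a local polynomial is how non-parametric
fits go wrong silently.

Per activity, the estimator map follows the selection that maximises
accuracy per activity class: Tian for
texting, calling and suitcase carrying; Kim for pocket and swinging.

## The synthetic generator

No recordings are deposited, so every stage is validated on synthetic
trials with exact ground truth. The generator reproduces the *structure*
the detector exploits, not wrist biomechanics:

* **Centre-of-mass archetype**: a fundamental at the step frequency with
  second and third harmonics shaped so the cycle is asymmetric — one sharp
  peak, one valley per cycle, and a substantial net velocity change per
  step. The asymmetry is essential, not cosmetic: a pure sinusoid
  integrates to zero mean velocity over a valley-to-valley slice, which
  would make the velocity feature pure noise and the K-regression
  unlearnable. Real torso acceleration is likewise asymmetric (heel
  strike). The harmonic weights and phases are frozen constants chosen by
  maximising the per-cycle net velocity subject to hard structural
  constraints: exactly one peak and one valley per cycle, no sub-threshold
  shelf or flat extremum neighbourhood that measurement noise could split
  into twin extrema, all verified on the 5 Hz-refiltered waveform across
  the whole 1.2–2.6 Hz cadence band (the detector can add valleys but
  never prune them, so spurious valleys are the one failure the method
  cannot repair).
* **Swing archetype**: `sin θ + 0.45·cos 2θ` at half the step frequency —
  two equal maxima per cycle, one deep minimum, and a secondary stationary
  point that stays positive, so the two-peaks-per-valley-pair structure is
  exact by construction.
* Waveform valleys start and end the trace with a quarter-cycle pad, so
  every ground-truth valley is an interior extremum; n steps produce
  n+1 valleys and exactly n (or 2 per swing cycle) peaks.
* Per-step lengths are drawn with 5% CV and rescaled to the exact trial
  total; the amplitude envelope is modulated proportionally, which is what
  makes K(v̄) learnable within a speed cluster.
* Gravity is added along a distinct per-activity orientation (that is what
  stage 2 sees); off axes carry low-amplitude AR(1) noise; the detection
  axis gets white noise of 0.15 m/s² SD; timestamps are 62.5 Hz with 1 ms
  jitter to exercise the resampler.

The dataset generator emulates repeated 20 m walks: speed levels are
cadences {1.4, 1.8, 2.2} Hz; mean step length grows sublinearly with
cadence (`∝ f^0.7` — fast walkers gain speed mostly from cadence) and
mildly with height (`∝ √h`); amplitude grows as `f^2.7` (oscillation
acceleration scales as frequency squared times displacement, and
displacement grows with step length). Step counts are rounded so the true
total is exactly 20 m. Heights are uniform on 1.5–1.9 m. The default
benchmark is 4 subjects × 5 activities × 3 speeds × 1 repetition = 60
trials: with fewer subjects the held-out subject's height is poorly
bracketed by the training pool and the (real, intrinsic) `√h` residual of
the Kim/Tian kernel pair dominates the distance error; four subjects keep
that residual a property of the method rather than of the draw.

Artifact injection attenuates a seeded fraction of interior valleys and of
peaks to 30% of their depth with a smooth raised-cosine window (below the
initial thresholds, above the 0.1 m/s² noise floor — exactly the failure
the corrections exist for) and can add spurious super-threshold bumps
inside reference intervals; ground truth is untouched.

**What passing these tests does and does not show.** The generator has the
archetypes' extremum structure, realistic amplitudes and plausible scaling
laws, but no soft-tissue artifacts, no orientation drift, no irregular
gait, no inter-step timing variability. Perfect classification and
near-perfect step counts on it demonstrate that the algorithms implement
their definitions and that the correction/feedback machinery does what it
claims under the failure modes it was designed for — not how accurate the
pipeline would be on recordings from a real cohort.

## Evaluation

`loso_evaluate()` is leave-one-*trial*-out, the standard protocol
for small datasets: per fold both SVM stages and all per-activity
K-models are retrained from the remaining trials, and the held-out trial
runs the full pipeline including feedback rerouting. Step accuracy is
`100·(1 − |detected − true|/true)` (symmetric in over/under-counting; no
single convention is established). Distance accuracy is the mean of
per-trial `100·(1 − |D_est − D_true|/D_true)`; NMSE is defined as
`100·Σ(D_est − D_true)²/ΣD_true²` — NMSE conventions vary, so the one used
is documented here and computed in `distance_metrics()`. Speed
bands (mean ± SD of the trial speed proxy) are computed **within**
activity: the proxy — the mean per-step velocity magnitude — scales with
each activity's signal amplitude, so pooling activities would partition
the trials by activity rather than by speed.

Typical problem sizes in the shipped tests: a 180-trial clean grid for
step-count exactness, a 60-trial artifact grid for the correction
comparison, and the 60-trial LOSO benchmark; on one core the whole suite
runs in minutes.

## Numerical choices and degenerate inputs

* Zero-phase filtering uses reflection padding (300 samples or series
  length − 1, whichever is smaller); transients decay geometrically with
  the pole radii, so a constant survives to machine precision.
* Local extremum detection is left-strict/right-non-strict: exactly one
  index per flat-topped plateau.
* Rank-deficient local WLS systems (e.g. a tiny bandwidth isolating fewer
  support points than coefficients) fall back to a 1e-8 ridge.
* A query landing in a sparse region of the training velocities widens its
  bandwidth geometrically until the effective local sample size supports
  the polynomial degree (a k-nearest-neighbour-style floor); a local fit
  that still returns a non-positive K — unphysical for a scale factor —
  falls back to the locally weighted mean. Both guards exist because an
  unconstrained degree-4 polynomial in a data gap can oscillate by orders
  of magnitude.
* A series whose detection signal never crosses zero in both directions is
  rejected ("not oscillatory") rather than thresholded nonsensically;
  fewer than two detected valleys raises "trial too short".
* Valley-gap correction recurses on the sub-gaps after each insertion and
  gives up (with a log entry) on gaps that stay empty after 10 relaxations.
* All indices are R's 1-based sample indices; step slices are the
  half-open interval `[valley_before, valley_after)` in samples.

## Known limitations

* The K-model conditions only on the velocity feature by design; the
  residual height dependence of the Kim (and, oppositely, Tian) kernels is
  therefore irreducible within the model class and shows up as a few
  percent of distance error in heterogeneous cohorts.
* Walking only: running, stairs and irregular gait are out of scope, as is
  real-time operation (the zero-phase filter alone is non-causal).
* The misclassification feedback assumes the two archetypes' one-vs-two
  peak dichotomy; gaits that genuinely alternate between them within one
  trial defeat a single per-trial majority.
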