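---
title: "Methods: head–thorax choreography analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: head–thorax choreography analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beechoreo)
```

This vignette documents the models and procedures implemented in `beechoreo`,
the parameter choices that matter, and what the synthetic validation does and
does not establish. The package targets marker-based recordings of the head
and thorax of freely flying insects, whose flights alternate between saccades
(fast turns) and intersaccades (gaze-stable translation).

## Rigid-body kinematics

**Body frame from markers.** Each body part carries three markers (left,
right, front). The body origin is their centroid; the y-axis is the unit
vector from the right to the left marker, so that with x forward the frame
(x, y, z) is right-handed and z = x × y points up for a level animal; the
x-axis is the unit component of (front − origin) orthogonal to y. Collinear or
coincident markers make the frame undefined and raise an error naming the
frame.

**Euler convention.** One convention is fixed package-wide: the body→world
rotation is `R = Rz(yaw) %*% Ry(pitch) %*% Rx(roll)` — the body is rolled
first, then pitched, then yawed. Decomposition confines pitch to
[−π/2, π/2]. At gimbal lock (|pitch| → π/2) yaw and roll are not separable;
the package sets roll to 0, lets yaw absorb the remaining rotation, and warns.
Yaw is unwrapped (made continuous across ±π) on construction of every pose
series, which matters before smoothing, interpolation, and differentiation.

**Angular velocity.** ω is obtained from the full rotation sequence as the
body-frame skew `unskew(Rᵀ dR/dt)` with central differences (one-sided at the
ends), not as the yaw rate. The two coincide when pitch = roll = 0, but only
the former remains correct under nonzero pitch/roll — precisely the regime the
top-view emulation is meant to probe. Central differencing of a rotation at
rate ω carries a relative bias of (ω/fps)²/6 (the sinc factor), about 2·10⁻⁶
at 100 °/s and 500 fps; tests assert rates at that accuracy, not at machine
precision.

**Smoothing.** Pose channels are smoothed with a penalized cubic smoothing
spline whose penalty is chosen to hit a target *effective degrees of freedom*
(default 150, matching common practice for ~10 s flights at 500 fps). This is
delegated to `stats::smooth.spline(df =, all.knots = TRUE)`, which performs
the penalty search; `lambda_df` equal to the sample count is the exact
zero-penalty (interpolating) limit and is special-cased to the identity.
Automatic selection of the degrees of freedom (e.g. by generalized
cross-validation) is intentionally out of scope: the value is a config input.

**Degraded recordings.** Two degradations common in practice are emulated.
(1) Low frame rate: decimate by the integer stride nearest fps/target (a
non-integer ratio is rounded, hence approximate), then re-interpolate onto
the original grid with an interpolating cubic spline — analyses then run at
the native grid as they would after upsampling a slow recording. Cubic
interpolation can overshoot slightly near sharp pulses, so peak velocities
are attenuated only up to a small overshoot, while signal energy strictly
decreases. (2) Top view: per frame, all marker z-coordinates are replaced by
their mean, which forces pitch = roll = 0 downstream exactly and leaves yaw
untouched; the operation is idempotent.

## Saccade segmentation and the benchmark

Segmentation uses a two-threshold hysteresis rule on |ω_z|: frames above the
seed threshold (default 372.42 °/s) start a saccade, which extends over
contiguous frames above the extension threshold (default 200.54 °/s). Both
turn directions count as saccades; a signed mode is available behind a flag
for single-direction analyses. No minimum duration or merge gap is applied.
Agreement between two labelings is the plain frame-wise accuracy.

The *benchmark* classifier thresholds the thorax velocity with the pair that
maximizes accuracy against head ground truth, searched exhaustively on a grid
(defaults: high 200–1000 °/s, low 50–1000 °/s, 5 °/s steps, low ≤ high — a
resolution that brackets the default thresholds). The search is implemented
incrementally (per low threshold, label runs are computed once and the
accuracy as a function of the high threshold is updated over runs sorted by
their maxima), which is algebraically identical to scoring every pair but
O(n·|low grid|); the equivalence is tested against direct evaluation. Ties are
broken deterministically toward the largest high, then the largest low; note
that when the data contain no run maximum between two adjacent grid values the
two pairs are label-equivalent and the larger wins, so "recovered" thresholds
are identified only up to the data's resolution.

## Windowed saccade classifiers

The classifier predicts the head's binary state at *t* from the thorax
velocity in a window of total width Δt centered on *t*; the sample count is
`2*floor(Δt*fps/2000) + 1`, using the floor of the half-width so odd
millisecond widths remain well-defined. Frames lacking a full window are
dropped, and windows never span flight boundaries. Flights are split
chronologically: the first 70 % (floor) of each learning flight trains, the
remaining 30 % validates, and the last flight is held out entirely.

Two families are provided behind one surface: a decision tree (`rpart`,
`cp = 0`, `minsplit = 2`, depth-limited) and a random forest (`ranger`,
probability forest, 100 trees by default — a conventional size, the forest
size being otherwise unconstrained — single-threaded with a recorded seed for
reproducibility). Classes are not reweighted; saccade/intersaccade frames are
reasonably balanced in saccade-dense flights, and a warning fires beyond
4:1. Hyperparameters (depth 1–20, window 0–50 ms) are grid-searched on
validation accuracy with ties toward the simpler model (smaller depth, then
smaller window). Evaluation reports accuracy, error rate, and the AUC of the
continuous scores with explicit ROC direction (a below-chance classifier is
reported below 0.5, never silently flipped); a binary benchmark labeling
yields the two-point ROC. Robustness sweeps rerun a pretrained classifier and
the fixed 500 fps-optimized benchmark on degraded flights (frame rate,
top view), always scoring against the original full-rate head ground truth.

## The velocity mapper and its anti-identity loss

The mapper is a three-layer feed-forward network: the velocity window (plus a
bias input) feeds N relu units (plus a constant bias unit), and two tanh
output units encode the predicted angular velocity as (cos θ, sin θ). The
encoding requires an angle: velocities are converted as θ = ω in radians per
sample interval (ω_rad/s ÷ fps), a data-free choice that keeps even extreme
saccade velocities (~5000 °/s at 500 fps ≈ 0.17 rad) far inside (−π, π); the
scale is configurable, and decoding (atan2 of the outputs, divided by the
scale) is insensitive to the output norm. The same scale is applied to the
input window, making inputs dimensionless and well-conditioned for the
±1/√fan_in uniform weight initialisation.

Training minimizes, over frames,

$$L = \sum_t \frac{\lvert \mathrm{enc}_{target}(t) - O(t)\rvert^2}
               {\lambda\,\lvert \mathrm{enc}_{source}(t) - O(t)\rvert^2 + \epsilon},
  \qquad \lambda = 0.5,\ \epsilon = 0.1,$$

which vanishes when the output reproduces the target and is maximal — the
denominator collapses to ϵ — exactly when the network reproduces its own
input (the "identity" solution), discouraging the degenerate mapping. The
optimizer is Adam (step 10⁻³, moment decays 0.9/0.999, minibatch 64, shuffled
each epoch from the run seed, 30 epochs); given (seed, data, config) training
is bit-reproducible. Initialisation is uniform ±1/√fan_in from the run seed.
A non-finite loss aborts with diagnostics. Hyperparameters (N in powers of two
up to 128, window 1–53 ms in 2 ms steps) are grid-searched on the median
unsigned error angle — the absolute angle between predicted and measured
direction encodings — on the 70/30 validation split, ties toward the smaller
network then the smaller window.

**Temporal shifts.** The shift τ (whole samples; requested milliseconds are
recorded alongside the realized sample shift) relates the observation window
to the predicted instant t − τ. For τ < 0 (*forecasting*) the window ends at
t, so the observations lie entirely before the predicted instant; for τ > 0
(*backcasting*) the window starts at t; τ = 0 uses the centered unshifted
pairing. A pair requires full support for both window and target, leaving
L − (span) − |τ| pairs. The correlation-versus-shift scan retrains a fresh
model per τ (same seed and config) on the learning flights and reports the
Pearson correlation between decoded prediction and target on the held-out
flight. Because the window placement changes with the sign of τ, lag scans
meant to localize a physiological delay are best run with a single-sample
window (Δt = 1 ms), for which all placements coincide; the scan then peaks at
the generating lag exactly. With the source leading the target by δ, the
source→target curve peaks on the forecasting side at τ = −δ and decays
sharply for backcasting shifts — the asymmetry that licenses a
predictive-causality reading.

## The synthetic flight generator

The generator defines the study conditions under which every stage is
validated. Saccade events follow a renewal process: a refractory gap (default
100 ms) plus an exponential holding time tuned so the mean rate is as
requested (default 4 events/s — saccade-dense, as in convoluted learning
flights near the nest). Each event adds to the head yaw velocity a Gaussian
pulse whose time integral equals the event amplitude (drawn uniformly from
±[20, 60]°), giving saccades lasting several tens of milliseconds whose peaks
(≈660–2000 °/s for the default 12 ms pulse SD) comfortably exceed the seed
threshold — bumblebee saccades being slower than the ~5000 °/s of flies. The
thorax receives a pulse of *equal integral*, centered 8 ms earlier (the
thorax initiates the turn) and 1.5× broader, hence lower-peaked; a negative
lead makes the head lead instead, which the causality experiments use.
Gaussian pulses are a modelling choice made for their analytic integrals; real
pulse shapes and the joint head/thorax lead-time distribution are not
identified by available descriptions, so these defaults are qualitative.

Measurement noise is an Ornstein–Uhlenbeck process (20 ms correlation time;
SD 30 °/s head, 80 °/s thorax) added to the *measured* velocity series only —
colored noise makes the thorax trace segment less cleanly, as real thorax
traces do. Yaw is the exact integral of the noise-free pulse train (via the
Gaussian CDF), so the net yaw change equals the summed event amplitudes;
ground-truth labels are the two-threshold segmentation of the noise-free head
velocity, keeping label noise out of downstream evaluations. Markers are laid
out as a rigid equilateral triangle (5 mm side) rotated by the pose and
translated along a gentle 3-D drift path, and the stored pose/velocity series
are *reconstructed from those markers* through the same code path a real
analysis would use — which makes `degrade()` at the native rate an exact
identity and the top-view transform exactly neutral for level flight.

What passing these tests shows — and does not. The generator reproduces the
*structure* the methods rely on (pulse-like saccades, a consistent thorax
lead, broader thorax pulses, colored noise, rigid marker geometry). It does
not reproduce flight dynamics, translation-coupled rotations, tracking
dropouts, marker occlusions, or soft-tissue marker motion. Results on
synthetic flights therefore validate the implementation and the qualitative
orderings (windowed classifiers beat pointwise thresholds; lag scans recover
a known lead), not the numeric performance to be expected on any particular
recording.

## Numerical choices and degenerate inputs

* Angles are radians internally; files store degrees; velocities are °/s
  everywhere. Frame indices are 0-based with half-open intervals in files and
  interval tables.
* Uniform time grids are enforced to 10⁻⁹ s; duplicated or non-monotonic
  timestamps and NaN rows are rejected with line numbers.
* Empty series, single-class training data, all-constant references, zero
  direction vectors, and shifts exceeding the series each raise a specific
  error or warning rather than propagating NaNs; the AUC of a single-class
  reference is reported as missing.
* Ties: threshold optimization → largest high, then largest low; classifier
  grid → smallest depth, then smallest window; mapper grid → smallest N, then
  smallest window.
* Problem sizes used in the test suite and acceptance script (six 10 s
  flights at 500 fps for the classifier study; two 6 s flights for lag
  scans; 10⁵ random signals for the segmentation oracle; 1000 random poses
  for the kinematics round trip) were chosen as the smallest sizes at which
  the qualitative results are stable across seeds.

## Known limitations

* The spline-based frame-rate emulation assumes integer decimation strides;
  other ratios are approximate by rounding.
* The mapper's input/output angle scale is a convention; analyses comparing
  error angles across frame rates must use the same scale.
* The benchmark threshold search optimizes accuracy only; AUC of the binary
  benchmark is reported from its two-point ROC and is not the optimization
  target.
* Left/right marker order fixes the sign of yaw; if a dataset labels the
  markers in the opposite convention, yaw (and ω_z) flip sign globally.
* No attempt is made at formal statistical tests of causality; the
  temporal-shift scan is a descriptive tool.
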