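---
title: "Analysing bimanual VR movements: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing bimanual VR movements: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vrmotion)
```

## The problem

Consumer VR systems track three rigid bodies — a head-mounted display (HMD)
and two hand controllers — each as a 6-DoF pose: position in meters and
orientation as Tait-Bryan angles, sampled here at 89 Hz. In a
telerehabilitation setting a user performs prescribed coordinated bimanual
gestures (reaching right, left, up, down and forward from a hands-at-shoulders
baseline), and the software must (i) calibrate its response to the user's
range of motion, (ii) find the movement repetitions in the stream, (iii)
summarise motor performance, (iv) learn which kinematic variables
characterise each gesture, and (v) classify, moment by moment, which gesture
is being performed. `vrmotion` implements that chain, together with a
synthetic session generator that stands in for human recordings.

## Kinematic model

Because a VR user can turn freely, controller poses are expressed relative to
the head frame \{H\} rather than the global frame \{G\}. With
$R^G_H$ the head's rotation and $P^G_H$ its position, a controller pose
$(R^G_C, P^G_C)$ maps to

$$R^H_C = (R^G_H)^\top R^G_C, \qquad
  P^H_C = (R^G_H)^\top (P^G_C - P^G_H),$$

the inverse of the homogeneous transform. The analysis substrate is a
30-column table per time step: HMD linear and angular velocity in \{G\}
(6), and per controller its position and orientation in \{H\} plus linear
and angular velocity in \{G\} (12 each). Velocities are forward finite
differences (a central scheme is available); angle series are unwrapped
first so angular rates carry no $2\pi$ wrap spikes.

Design choices worth stating:

* **Tait-Bryan convention.** The logging runtime does not declare its
  rotation order; we default to intrinsic z-x-y (the Unity/Oculus order) and
  expose `"xyz"` and `"zyx"` as alternatives. Saliency results depend on
  this choice, since the loading-gap rule operates on per-angle variables.
* **Angular velocity** is the per-angle rate of the unwrapped Tait-Bryan
  angles, not a body-frame rate vector, matching the per-angle layout of
  the variable table.
* **Stencil loss.** The forward difference costs the final row; per-step
  labels are truncated to match. Velocity samples are attributed to the
  left node.
* **Frame equivariance.** Under a rigid change of the global frame the
  \{H\}-frame columns are invariant and the linear-velocity columns rotate
  with the frame. Per-angle Tait-Bryan *rates* are not equivariant under a
  fixed global rotation (Euler-angle rates do not transform linearly), so
  the test suite asserts equivariance for linear velocities only.

## Calibration

During calibration each gesture is repeated five times. Per axis, the
average excursion is
$\bar D = \tfrac{1}{5}\sum_{n=1}^{5}\max_t |P^G_h(t) - P^G_H(t)|$, where
$P^G_h$ is the controller midpoint; cursor thresholds sit at a fraction
(default 0.25) of $\bar D$, so users with a smaller range of motion drive
the interface with proportionally smaller movements. Exceedance is measured
against the instantaneous head position, not a frozen calibration origin.
The sign map (+x → left, −x → right, +y → up, −y → down, +z → select) is
fixed in one place; pulling towards the body maps to no command. An axis
with zero average excursion is disabled with a warning rather than firing
on noise.

## Segmentation

Movement is detected from the speed statistic
$\Omega(t)$ = mean of the two controllers' instantaneous speeds
$\|\Delta P\|/\Delta t$ (max and midpoint-speed rules are available; for
symmetric bimanual gestures the mean is robust to one-sided jitter).
Intervals are maximal runs with $\Omega$ above 0.077 m/s lasting strictly
longer than 0.2 s — the study defaults, kept per-session configurable
because they are user-specific in practice; a run needs
$\lceil 0.2/\Delta t\rceil + 1$ samples. Consecutive interval pairs
(outward excursion, return) plus the enclosed dwell form one repetition
segment; labels follow the fixed protocol order. A clean 5×5 calibration
yields 25 segments. Because the minimum-jerk speed profile spends its first
and last few samples below the threshold, detected boundaries lag the true
movement onset by ~4–5 samples at 89 Hz; this is a property of the
threshold rule, and the tests allow for it explicitly.

## Motor-performance metrics

Per segment and hand, on the two movement intervals only: range of motion
(max displacement along a chosen \{H\}-axis or in 3-D; measured from the
interval's first sample by default, with a distance-from-headset option),
mean speed, smoothness, and path length. Smoothness is defined as mean
speed divided by maximal instantaneous speed, a number in (0, 1]; published
tables in this literature often report values around 1.9–2.5, consistent
with the reciprocal max/mean (a minimum-jerk reach gives exactly 1.875), so
the reciprocal is available via `reciprocal = TRUE` while the stated
definition stays the default.

## Saliency by spectral and loading gaps

Within each segment the 30 series are normalised by their own SD (sample
SD; zero-SD columns pass through flagged), and the population covariance
$K_{ij} = \tfrac{1}{T}\sum_t (s_i - \bar s_i)(s_j - \bar s_j)$ is
eigendecomposed. The number of dominant components is set by the *spectral
gap* — the largest difference between consecutive descending eigenvalues,
ties broken toward fewer components. The first eigenvector's absolute
loadings are sorted and cut at their largest consecutive drop; the
variables before the cut are the segment's salient set. Per gesture, the
five repetitions' sets are combined by union with occurrence counts.
Eigenvector sign is irrelevant throughout. The package derives salient sets
from data and hard-codes none.

## Windowed features and classification

A 13-step (0.15 s) stride-1 window yields, per position: the means of the
12 relative-pose variables, the sample SDs of the 6 relative orientation
angles, and the Pearson correlations of the three homologous angle pairs
across hands — 21 features. The window's true class is the mode of its 13
step labels (ties resolved deterministically toward the class occurring
earliest in the window). Two published descriptions of the SD feature set
conflict (six orientation SDs vs right-controller position+orientation);
only the former is consistent with a 21-feature total, so it is the
default and the other reading is available through `feature_spec()`.
A zero-variance column in a correlation pair yields a flagged 0.

The classifier is bootstrap aggregation over full-depth recursive-
partitioning trees (Gini, all features eligible at every split, as is
standard for bagging): each of `n_trees` (default 100 — the tree count is
not fixed by the source methodology) trees trains on a with-replacement
resample of training-set size; prediction is simple majority vote with
ties broken by class order. Evaluation is stratified, seed-shuffled
5-fold cross-validation with pooled out-of-fold predictions. Stratified
pooling shares temporally adjacent (overlapping) windows across folds;
participant- or segment-grouped folds can be supplied via `folds` when
that leakage matters for a claim. Feature importance is out-of-bag
permutation: per tree, the increase in error on its out-of-bag instances
when one feature's values are permuted, summed over trees. With exactly
duplicated features the deterministic first-column split tie-break
concentrates importance on the first copy — correlated features share
importance less gracefully than decorrelated ones, which is documented
rather than hidden.

## The synthetic generator

`generate_calibration_session()` emulates the calibration protocol: five
gestures in protocol order, five out-and-back repetitions each, ~1 s
baseline dwells, 89 Hz. Reaches follow minimum-jerk profiles
($s(\tau) = 10\tau^3 - 15\tau^4 + 6\tau^5$), giving closed-form oracles:
one-way mean speed $A/T$, peak speed $1.875\,A/T$, smoothness
$1/1.875 \approx 0.533$. Amplitudes (0.4–0.65 m, lead/trail asymmetry on
lateral reaches) and the 0.7 s one-way duration are set so that mean
speeds land near 0.86 m/s for a 0.6 m reach, matching the magnitudes
reported for healthy adults performing these gestures. Each gesture
couples a secondary position arc (reaches are not straight lines) and
programmed Tait-Bryan excursions — the strongly driven angles are recorded
as ground truth so saliency recovery is testable.

Noise is modelled in three parts, each chosen for the physical scale it
represents:

* **Position jitter, 0.25 mm i.i.d.** Sample-to-sample optical-tracking
  jitter. This is deliberately the *jitter* scale, not the mm-scale
  absolute accuracy often quoted for such systems: the speed statistic is
  a finite difference, so i.i.d. position noise of SD $\sigma$ produces a
  speed floor of roughly $\sigma\sqrt{2}\,\mathbb{E}\|N_3\|\,f_s \approx
  570\,\sigma$ m/s at 89 Hz. A 2 mm jitter would give ~0.4 m/s — five
  times the 0.077 m/s movement threshold — so a system on which that
  threshold works at all must have sub-millimeter jitter.
* **Angle jitter**: 0.5° on controllers, 0.02° on the HMD. The HMD value
  matters doubly: head attitude noise multiplies into every head-relative
  position through the ~0.5 m head-to-hand lever arm, and an IMU-fused
  headset is far steadier than optically corrected hand controllers.
* **Movement-locked tremor**: 7–11 Hz oscillation with amplitude following
  the speed profile (signal-dependent motor noise — absent at rest, so the
  dwell-time speed floor is untouched), ~8 mm and ~3° at peak speed, with
  independent frequency and phase per channel. Its main analytical role is
  realism in the velocity columns: noiseless differentiated trajectories
  would be implausibly coherent.

`generate_impaired_session()` scales one arm's amplitude and optionally
splits each excursion into several minimum-jerk submovements separated by
micro-pauses (a multi-peaked speed profile), degrading smoothness and range
of motion on the affected side only; it exercises metric sensitivity and
makes no clinical claim.

What the generator does *not* emulate: joint-chain biomechanics (it works
at end-effector level, which is all the sensors observe), head macro-motion,
temporally correlated sensor drift, gesture-timing variability between
repetitions, and between-subject variability. Tests passing on this
generator therefore establish that the pipeline recovers what it is defined
to recover under protocol-conformant input — not that human data are this
clean.

## Numerical conventions

Indices into the speed series and segments are 0-based half-open (converted
to R's 1-based rows at the point of use); velocity rows align with the left
node of each difference. Eigen-decomposition uses the symmetric path with
descending eigenvalues; gap ties break toward fewer components. All
stochastic steps (session noise, bootstrap, fold shuffles, permutations)
take explicit integer seeds and restore the caller's RNG state, so a fixed
seed makes every artifact byte-reproducible.

## Problem sizes used in the shipped checks

The structural checks run on full 5×5 sessions (~5,400 steps, ~60 s).
Segmentation stability uses 100 independent seeds; the dominant-component
check uses 100 segments from four sessions. Classifier checks subsample the
window stream (every 3rd–4th window) and use 15–40 trees; these sizes give
the same qualitative results as the full-stream, 100-tree configuration
while keeping the whole suite quick on a single CPU.

## A short worked example

```{r example, eval = FALSE}
sim <- generate_calibration_session(reps = 5, seed = 1)
tab <- assemble_variable_table(sim$session)
om  <- omega_series(as.matrix(sim$session$right[c("x", "y", "z")]),
                    as.matrix(sim$session$left[c("x", "y", "z")]), 1 / 89)
seg <- build_segments(detect_intervals(om))
nrow(seg)                                   # 25 repetition segments
agg <- aggregate_saliency(segment_saliency(tab, seg))
agg$abduction_right                         # angle-dominated salient set
ds  <- build_window_dataset(tab)
ev  <- kfold_evaluate(ds[setdiff(names(ds), c("class", "window_start"))],
                      ds$class, k = 5, n_trees = 100, seed = 1)
ev$accuracy
```

## Known limitations

* The pipeline analyses calibration-phase data; free-interaction
  segmentation is out of scope.
* Stratified CV over stride-1 windows shares near-duplicate windows across
  folds; accuracies under this split are optimistic relative to
  subject-held-out evaluation, which is why grouped folds are exposed.
* Saliency depends on the assumed Tait-Bryan convention of the logs.
* The smoothness score direction (mean/max vs max/mean) is a genuine
  ambiguity in the source literature; both are provided.
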