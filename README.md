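# vrmotion

Kinematic analysis and classification of coordinated bimanual arm movements
recorded by consumer virtual-reality hardware — a head-mounted display (HMD)
and two hand controllers, each streaming a 6-DoF pose (position in meters,
orientation as Tait-Bryan angles) at 89 Hz. The package targets
telerehabilitation research, where prescribed bimanual gestures (reach
right, left, up, down, push forward) must be calibrated to a user's range
of motion, detected in the stream, scored for motor performance, and
classified automatically so a clinician can monitor exercise remotely.

## What it computes

Because a VR user can turn freely, the analysis works on controller poses
relative to the head frame {H}, via the inverse homogeneous transform
R<sup>H</sup><sub>C</sub> = (R<sup>G</sup><sub>H</sub>)<sup>T</sup>
R<sup>G</sup><sub>C</sub>,
P<sup>H</sup><sub>C</sub> = (R<sup>G</sup><sub>H</sub>)<sup>T</sup>
(P<sup>G</sup><sub>C</sub> − P<sup>G</sup><sub>H</sub>). From there:

- **30-variable table** per time step: HMD linear/angular velocity in {G};
  per controller, position and orientation in {H} plus linear/angular
  velocity in {G} (finite differences of unwrapped angles).
- **Calibration**: per-axis average excursion D̄ of the controller midpoint
  relative to the head over 5 repetitions; cursor thresholds at 0.25·D̄.
- **Segmentation**: the speed statistic Ω (mean of the two controllers'
  instantaneous speeds) thresholded at 0.077 m/s for longer than 0.2 s;
  interval pairs (excursion + return) become labelled repetition segments.
- **Motor performance** per segment and hand: range of motion, mean speed,
  smoothness (mean/max speed; reciprocal available), path length.
- **Saliency**: per-segment SD-normalisation, covariance eigenspectrum,
  spectral-gap selection of dominant components, loading-gap selection of
  salient variables.
- **Classification**: 13-step (0.15 s) sliding windows → 21 features
  (12 relative-pose means, 6 orientation SDs, 3 cross-hand angle
  correlations), labelled by the step-label mode; bagged full-depth
  decision trees with majority vote, stratified 5-fold cross-validation,
  and out-of-bag permutation importance.
- **Synthetic sessions**: a generator that emulates the calibration
  protocol with minimum-jerk reaches, programmed orientation couplings,
  realistic sensor jitter and movement-locked tremor, plus an "impaired
  arm" variant — so the whole chain is testable without human data.

## Worked example

```r
library(vrmotion)

sim <- generate_calibration_session(reps = 5, seed = 1)   # 5 gestures x 5 reps
tab <- assemble_variable_table(sim$session)               # 30 columns
om  <- omega_series(as.matrix(sim$session$right[c("x", "y", "z")]),
                    as.matrix(sim$session$left[c("x", "y", "z")]), 1 / 89)
seg <- build_segments(detect_intervals(om))
nrow(seg)
#> [1] 25

aggregate_saliency(segment_saliency(tab, seg))$abduction_right
#>     variable count
#> 1  alpha_H_L     5
#> 2  alpha_H_R     5
#> ...                  (orientation angles of both controllers dominate)

ds <- build_window_dataset(tab)                           # 21 features/window
ev <- kfold_evaluate(ds[setdiff(names(ds), c("class", "window_start"))],
                     ds$class, k = 5, n_trees = 100, seed = 1)
ev$accuracy
#> [1] 0.9942614
```

The 25 segments are the 5×5 calibration repetitions; the salient set shows
that controller orientations (γ, α, β of both hands), not raw positions,
carry the coordinated variance of a lateral reach; the cross-validated
window classification accuracy on the synthetic session is ~0.99, with most
confusions at movement onsets/offsets where a window straddles two classes.

`run_pipeline(pipeline_config(seed = 1), out_dir = "out")` runs every stage
and writes CSV/JSON artifacts; `inst/scripts/vrmotion.R` wraps the same
calls for shell use.

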