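# duotrack

Dual-locking multi-object tracking for livestock video monitoring, in R.

## The problem

Per-animal health monitoring in intensive pig farming needs every
individual followed through video for minutes at a time. Detectors drop
out whenever animals occlude each other, and same-breed pigs look alike,
so naive tracking-by-detection swaps identities — and every identity
switch corrupts the per-animal statistics downstream. `duotrack`
implements a tracker built for identity retention under occlusion:

- a **primary locker**: an 8-dimensional constant-velocity Kalman filter
  per target (state `(cx, cy, a, h)` plus velocities), appearance
  re-identification against a bounded feature gallery, Mahalanobis gating
  (chi-square 0.95, 4 dof) and a tiered matching cascade with IoU fallback;
- an **auxiliary locker**: a kernelized correlation filter (KCF) over HOG
  features — ridge regression over all circular shifts of the target
  patch, solved in the Fourier domain — that keeps emitting position
  estimates through detector dropouts ("gap filling", budgeted at 20
  consecutive frames);
- **conflict coverage**: overlapping lockers (IoU > 0.5) are arbitrated by
  the score `S = 0.4·C + 0.3·H + 0.3·L` (current confidence, historical
  stability `N_tracked/N_total`, normalized trajectory maturity); the
  lower-scoring locker is removed.

Around the tracker the package provides CLEAR-MOT / IDF1 evaluation with
locking-duration statistics, detector loss formulas (BCE, CIoU, weighted
composite), letterbox / adaptive-resize preprocessing, a synthetic
pen-scene generator with a calibrated detection-noise emulator, and a
pure-software model of the pan-tilt gimbal serial protocol
(`#X$Y\r\n` framing, 200-byte receive buffer state machine).

## A worked example

```r
library(duotrack)

# a 4-target synthetic pen scene with occlusion-driven detection dropouts
sim <- run_simulate(scenario_config(n_targets = 4, n_frames = 150, seed = 7))
run <- track_detections(sim$detections, n_frames = 150)
glance(run)
#> # A tibble: 1 x 7
#>   n_frames n_ids n_boxes n_filled fill_fraction n_conflict_removals n_resyncs
#>      <dbl> <int>   <int>    <int>         <dbl>               <int>     <int>
#> 1      150     4     592        6        0.0101                   0         6

evaluate_tracking(sim$scene$gt, run$results)
#> <mot_eval> MOTA 98.67%  MOTP 89.36%  IDF1 99.33%  IDSw 0  Frag 0  FP 0  FN 8
```

Four animals over 150 frames: the tracker emits 592 boxes of which 6 are
gap-filled (detector dropouts bridged by the auxiliary locker) and
re-synchronizes after gaps 6 times. Against ground truth that yields 98.7%
multi-object tracking accuracy with zero identity switches; the 8 false
negatives are the first two frames of each track, where confirmation
(3 consecutive hits) is still pending.

`autoplot(run)` draws the trajectories with gap-filled stretches as open
points; `tidy(run)` returns the per-box table; `run_track()` writes
MOT-Challenge files plus a detected/filled sidecar and a config snapshot.
A thin CLI with `simulate` / `track` / `evaluate` / `ablate` /
`gimbal-stream` subcommands is installed at `inst/cli/duotrack`.

## Scope

The package consumes detections (MOT-Challenge text format, or images plus
a pluggable detector/feature extractor); training the detection and
re-identification networks, the farm-data pipeline, and the
microcontroller firmware behind the serial protocol are out of scope. The
reference appearance extractor is a deterministic, weight-free
color/gradient histogram so the pipeline runs without any learned weights;
any extractor with the same signature can be plugged in via
`duotrack_config(feature_extractor = ...)`.
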