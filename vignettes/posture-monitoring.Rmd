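---
title: "Quaternion joint angles and posture monitoring: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quaternion joint angles and posture monitoring: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imuposture)
```

## The problem

Sustained or repeated postures well outside neutral — occupational guidance
puts the risk threshold around 20–30 degrees from the natural state — are a
major driver of musculoskeletal disorders in physically demanding work.
Wearable 9-axis IMUs (accelerometer + gyroscope + magnetometer with an
on-board fusion filter) make continuous field monitoring practical: each
sensor streams a fused orientation as a unit quaternion, and joint angles
fall out of the *relative* orientation of adjacent body segments.

`imuposture` implements that pipeline in software only. Orientations arrive
pre-fused (sensor fusion is explicitly out of scope); everything downstream
— quaternion algebra, joint-angle measurement, re-zeroing calibration, the
13-segment body model with range-of-motion limits, the packet dialect, and
a synthetic-motion simulator that stands in for the hardware — is
implemented and tested here.

## Conventions

All public angles are degrees. Quaternions are scalar-first `(w, x, y, z)`,
matching the wire names `wq/xq/yq/zq`, and are canonicalized to `w >= 0`
(`q` and `-q` are the same rotation). The Euler decomposition is **intrinsic
Z–X′–Y″** (`R = Rz(z) Rx(x) Ry(y)`), applied identically everywhere. The
original system never states its Euler order and its published baselines
cannot disambiguate one, so this is a documented convention, not an
inference; every number the package produces is well-defined under it, and
every conversion is checked against an independent rotation-matrix oracle
in the test suite.

**Gimbal lock.** When the middle (X) angle approaches ±90°, the Z and Y
axes align and the decomposition loses a degree of freedom. The
deterministic tie-break: when `|sin x| > 1 − 1e−9`, set `z = 0` and assign
all residual rotation to `y`. Recomposition is exact (the returned triple
always reproduces the input rotation); the split between `z` and `y` is the
convention. The middle angle is computed with the `atan2` form
`atan2(R32, ||(R31, R33)||)` rather than `asin`, which stays
well-conditioned through the lock. All `acos`/`asin` arguments are clamped
to `[-1, 1]`, so no input produces `NaN` — the published Method-1 grids
contain `NAN` cells in exactly the column whose reference axis is parallel
to the motion (where the dot product sits at 1 up to rounding); clamping
makes those cells read 0 instead, and the package treats the printed `NAN`s
as an artifact of the original implementation.

## The three measurement methods

For a parent segment `p` and child segment `c` with world orientations
$q_p, q_c$:

- **Method 1** rotates a reference unit axis by both orientations and
  returns $\arccos(\hat{u}_p \cdot \hat{u}_c)$ — unsigned, in `[0, 180]`,
  blind to the rotation component about the reference axis itself.
  `method1_axes()` evaluates it on the three basis axes, which is why a
  single-axis motion shows up identically in the two orthogonal columns
  and as ~0 in the parallel one.
- **Method 2** (the method of choice) decomposes the relative rotation
  $q_p^{-1} q_c$ into Euler angles: signed, one clearly active axis per
  clinical motion, invariant under any common world rotation, and
  antisymmetric under swapping parent and child.
- **Method 3** reads the child's *stored local rotation*, which in a
  skeletal rig includes the rest-pose offset: the package computes
  `euler(offset ⊗ motion)`. With a zero offset (knee, elbow) it coincides
  with Method 2; with a posed rig (wrist) its baseline is shifted by the
  rest pose — which is exactly the behaviour the published wrist grids
  show.

A subtlety worth recording: the published grids show near-zero Method-2
baselines *and* large Method-3 baselines for the wrist. Those are only
consistent if the physical sensors' world frames coincide at neutral while
the avatar rig stores a non-zero rest local rotation. The simulator
therefore emits aligned world frames, and the rig offset enters Method 3
only. The original hand rest pose is not published; `default_rig("wrist")`
uses the documented upper-arm offset `(-80, 0, 0)` as a synthetic stand-in,
so wrist Method-3 baselines are non-zero but not numerically identical to
the published ones.

## Calibration (re-zeroing)

IMUs drift slowly. The monitor re-zeroes on a trigger (the "C button"): it
captures the current Euler reading of every active segment atomically and
subtracts it per axis from subsequent readings, wrapping into `[-180, 180)`
(half-open by choice; the boundary is not fixed by the source). The
subtraction is deliberately per-axis in Euler space — that is the
re-zeroing rule the original monitoring loop applies — which is an exact
rotation composition only for single-axis motion. `apply_calibration`
after `capture_reference` of the same reading returns exactly `(0, 0, 0)`,
and after a simulated 0.5°/min drift a mid-stream re-capture returns the
steady pose to zero within 1e-9.

## The body model and violation events

The model mirrors the original array of 13 per-segment structs (quaternion;
rotation/correction/position Euler triples; sensor number; name). The 13
names — head, chest, pelvis, both upper/lower arms, hands, upper/lower
legs — are a documented assumption: the source rotates head, chest, hips,
upper arms and upper legs and measures wrist/knee/elbow joints but never
enumerates all 13 allocations.

Scenario presets follow the dropdown's 0–4 coding (none, standing, sitting,
joint movement, lifting); scenarios 1–4 monitor head, chest and pelvis with
a ±30° range on every axis (the relaxed spinal threshold). Pivot loads the
X axis on all three segments; flexion and axial rotation load Y/Z for head
and chest but Z/Y for the pelvis. Limit comparison is strict (`>`): exactly
30° does not flag (the boundary case is unspecified in the source; a strict
rule avoids flagging the nominal limit pose itself).

A **violation event** is a flagged excursion sustained for at least
`min_duration` seconds (default 5 s — "sustained" is never quantified in
the source, so this is configurable). Within a segment/axis series, flagged
samples chain into one run while their spacing stays strictly under two
sample periods: timing jitter below one extra period is bridged, while a
fully dropped sample or an in-range sample splits the run. This is the
conservative reading of "gaps shorter than one sample period are bridged";
the split cases are pinned by construction tests.

## The synthetic-motion generator

The generator emulates the fused output of the wearable at a configurable
output rate within the device's 1–60 Hz streaming range (default 60 Hz, the
top rate). A scripted motion ramps linearly to the target angle and holds
it; a goniometer sweep holds one steady pose per target of the grid
`{0, 10, 20, 30, 40, 50}`°, the published validation protocol.

- **Noise** is an isotropic small rotation composed onto the true
  orientation in the sensor frame, drawn as a rotation vector with i.i.d.
  `N(0, σ²)` components (degrees). This keeps the noise
  convention-independent (no Euler axis is privileged) *and* gives each
  Euler axis a Gaussian perturbation of standard deviation exactly σ, which
  the tests verify at n = 10⁴ (a single-angle/uniform-axis formulation
  would have given σ/√3 per axis, contradicting the stated per-angle
  magnitude). Default σ = 0; the validation criteria use σ = 1°, a
  realistic static-orientation error for a well-calibrated consumer IMU.
- **Drift** is a linear bias ramp on the motion axis in degrees/minute
  (default 0; the calibration scenario uses 0.5°/min, a slow heading-style
  drift). Linearity is a deliberate simplification — real drift is neither
  linear nor axis-locked — sufficient to exercise re-zeroing end to end.
- **Determinism**: all randomness flows through an explicit seed; the same
  seed yields a bit-identical packet stream, and the generator restores the
  caller's RNG state.

What a green test does *not* establish: the generator does not simulate raw
inertial channels, fusion-filter transients, magnetic disturbance,
soft-tissue artefact, or sensor-to-segment misalignment. Green validation
criteria certify the *software pipeline* (geometry, conventions, wiring),
not clinical accuracy of any physical sensor.

## Validation tables and accuracy summaries

`build_validation_table` evaluates each method at every held pose and
stores the circular mean over the hold samples as the cell — the analogue
of reading a steady value off the display, decided before any criterion was
run. Per-sample robustness is tested separately (mean absolute deviation of
Method 2 from the commanded grid ≤ 2° at σ = 1°).

The published headline figures ("94% / 96% accuracy") are never defined, and
no candidate metric applied to the printed grids reproduces them
convincingly (e.g. the range-normalized percent over the full-body grid
computes to ~99.3%). `accuracy_metrics` therefore reports several clearly
labelled statistics — MAE, maximum absolute error, the within-±1°
proportion, and the range-normalized percent `100·(1 − MAE/50)` — rather
than claiming to reproduce the published percentages. Cells printed as
`NAN`/`N/A` are excluded from all summaries. The nine published grids ship
as plain-text fixtures (`load_printed_table(2:10)`) and are checked
cell-for-cell against an independent transcription in the test suite.

## Numerical choices

- Quaternions renormalize only when the norm strays beyond 1e-12 of 1
  (tighter than the 1e-6 contract), so already-unit components — e.g. from
  a parsed packet — pass through bit-exactly; this is what makes
  `serialize ∘ parse` byte-stable.
- Packets serialize numbers with `%.17g`, the shortest-safe precision for
  lossless double round trips; CSV logs do the same.
- On ingest a packet quaternion must be unit within 1e-3 (renormalized
  thereafter); worse than that indicates a corrupted stream and is
  rejected with the offending field named.
- Timestamp pairing tolerance for joint measurement defaults to half a
  sample period at the configured rate.
- `wrap_angle` is `((a + 180) mod 360) − 180`, exact at the boundary
  (`wrap_angle(180) == -180`) and vectorized.

## Known limitations

- Per-axis Euler calibration is approximate for simultaneous multi-axis
  excursions (faithful to the source algorithm; a quaternion-space
  calibration would compose exactly but would not match the system being
  modelled).
- Euler-order choice is a convention; numbers are comparable across this
  package but not directly against engines using another order.
- The wrist Method-3 baseline is a labelled synthetic stand-in (see above).
- The monitor is an offline/streaming-replay implementation; no socket
  transport is bound (a file of JSON lines is the transport, per the
  protocol's design).
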