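# imuposture

Posture monitoring and joint-angle measurement from wearable-IMU
orientation streams.

## What this is for

Sustained awkward postures — more than roughly 30° from neutral, held for
long periods — are a leading cause of work-related musculoskeletal
disorders. Body-worn 9-axis IMUs make continuous monitoring practical:
each sensor's fusion filter emits a unit quaternion orientation, and the
angle of a joint is the *relative* orientation of the two segments it
connects. This package implements the full software side of such a
monitor, for ergonomics and rehabilitation work where the sensors (or a
simulator standing in for them) stream orientations:

- **Quaternion core** — exact algebra on unit quaternions
  $\hat q = \cos(\theta/2) + (u_x i + u_y j + u_z k)\sin(\theta/2)$,
  scalar-first `(w, x, y, z)`, with a fixed intrinsic Z–X′–Y″ Euler
  convention and a deterministic gimbal-lock policy.
- **Three joint-angle methods** over parent/child segment pairs:
  (1) $\arccos$ of the dot product of rotated reference axes (unsigned);
  (2) Euler angles of $q_{parent}^{-1}\,q_{child}$ (signed — the default
  method); (3) the child's local rotation including its rig rest-pose
  offset.
- **Re-zeroing calibration** — capture a reference pose, subtract per axis,
  wrap into `[-180, 180)`; cancels slow sensor drift on demand.
- **13-segment body model** with scenario presets (none / standing /
  sitting / joint movement / lifting), ±30° safe ranges on head, chest and
  pelvis, and sustained-violation events.
- **Streaming** — newline-delimited JSON packets
  (`{"id":"s1","t":0.0,"wq":1,"xq":0,"yq":0,"zq":0}`; `wq` is the real
  component) and lossless CSV logs.
- **Synthetic motion** — a seeded simulator (1–60 Hz, rotational noise,
  linear drift) replacing the hardware, plus a goniometer-sweep validation
  harness over the grid {0, 10, 20, 30, 40, 50}° with accuracy summaries.

See `vignettes/posture-monitoring.Rmd` for the model, conventions, and the
design decisions behind them.

## Worked example

Simulate the bench validation protocol — elbow flexion posed at each
goniometer target with 1° rotational noise — and tabulate all three
methods:

```r
library(imuposture)

sw  <- simulate_goniometer_sweep("elbow", "flexion", sigma = 1, seed = 42)
tab <- build_validation_table(sw)
round(as.data.frame(tab)[, c("target","m1_x","m1_y","m1_z","m2_x","m2_y","m2_z")], 1)
#>   target m1_x m1_y m1_z m2_x m2_y m2_z
#> 1      0  1.8  1.8  1.8 -0.1  0.0  0.1
#> 2     10 10.0  1.6 10.0  0.2  9.9 -0.2
#> 3     20 19.9  1.7 19.9  0.0 19.9 -0.1
#> 4     30 30.1  1.7 30.1  0.0 30.1 -0.3
#> 5     40 39.9  1.8 39.9  0.0 39.9  0.0
#> 6     50 50.1  1.7 50.1 -0.1 50.1  0.0
```

Elbow flexion is a Y-axis motion here, so Method 2 tracks the grid on its
`m2_y` column with the other axes near zero, while unsigned Method 1 reads
the grid on both reference axes orthogonal to the motion (`m1_x`, `m1_z`)
and only the noise floor on the parallel one. Summarize the active axis:

```r
str(accuracy_metrics(tab, "m2_y"))
#> List of 5
#>  $ mae             : num 0.0719
#>  $ max_abs_error   : num 0.133
#>  $ within_1deg     : num 1
#>  $ percent_accuracy: num 99.9
#>  $ n_cells         : int 6
```

`mae` is the mean absolute deviation from the goniometer targets in
degrees; `percent_accuracy` is the range-normalized `100·(1 − MAE/50)`
(one of several labelled statistics — the historical headline "accuracy
percent" for this protocol was never defined, so none is claimed).

Monitoring: a head pivot to 35°, held for 8 s under the lifting scenario
(±30° limits, 5 s sustained threshold) produces exactly one violation
event:

```r
packets <- script_motion(motion_profile(segment = "s1", motion = "pivot",
                                        target = 35, ramp_time = 1,
                                        hold_time = 8, rate = 60))
monitor_stream(packets, scenario_config(4))$events
#>   segment axis start      end peak
#> 1    head    x  0.85 8.983333   35
```

The embedded copies of the nine published goniometer-comparison grids are
available via `load_printed_table(2:10)`.

## Command line

A thin CLI wraps the same functions (`simulate`, `replay`, `monitor`,
`validate`):

```sh
cli=$(Rscript -e 'cat(system.file("cli/posture.R", package = "imuposture"))')
Rscript "$cli" simulate --segment=head --motion=pivot --target=30 --out stream.jsonl
Rscript "$cli" monitor  --in stream.jsonl --scenario=4 --events-out events.csv
Rscript "$cli" validate --joint=elbow --motion=flexion --sigma=1 --seed=1 \
                        --table-out table.csv --metrics-out metrics.json
```

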