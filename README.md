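# ulmtrack

Microbubble tracking for super-resolution ultrasound (ultrasound
localisation microscopy, ULM) with a constant-acceleration Kalman motion
model.

## The problem

ULM reconstructs microvasculature below the acoustic diffraction limit by
localising intravascular microbubbles frame by frame and linking the
localisations into tracks.  At clinical frame rates (15–35 Hz) a bubble
moves hundreds of micrometres between frames, and cardiac pulsatility
swings its speed several-fold within each cycle, so a tracker that assumes
constant velocity between frames mispredicts exactly where the flow is most
dynamic.  `ulmtrack` is for researchers who have per-frame localisation
tables (or want to simulate them) and need tracks, super-resolution maps,
and quantitative tracking metrics.

## The method

Each bubble carries a six-dimensional Kalman state
`S = [x, vx, ax, y, vy, ay]` propagated per axis by

    [1  dt  dt^2/2]
    [0   1  dt    ]
    [0   0  1     ]

with white-jerk process noise `Q = G G' sigma_a^2`, `G = [dt^2/2, dt, 1]'`.
A track–detection pair is scored by the reciprocal Gaussian likelihood
`cost = 1 / N(z; H S_pred, H P_pred H' + R)` and pairs beyond a chi-squared
Mahalanobis gate are forbidden; frame-to-frame association minimises the
total cost over one-to-one matchings.  New tracks are born from triplets of
unmatched detections across three consecutive frames, selected by the
normalised vector-difference cost `||L23 - L12|| / (||L23|| + ||L12||)` and
seeded with the central-difference velocity `(L12 + L23) / (2 dt)` and
second-difference acceleration `(L23 - L12) / dt^2`.  Between linked
localisations, trajectories are interpolated along the quadratic implied by
the Kalman velocity and the unique acceleration hitting the next
localisation, which yields density, speed, and spatial speed-gradient maps.
A constant-velocity baseline (`model = "linear"`) shares every other
component so the motion models can be compared head to head.

The package also ships the pulsatile microvasculature simulator used to
validate all of this: seeded branching vessel trees and single tortuous
vessels, a raised-cosine pulsatile speed law with configurable mean speed,
heart rate and peak acceleration, ground-truth identities, and metrics
(pair TPR/FNR, interpolation error, velocity error, SSIM, Fourier ring
correlation resolution).

## Worked example

```r
library(ulmtrack)

tree  <- make_vessel_tree("branching", seed = 3)
flow  <- flow_profile(s0 = 3, a_max = 112.5, heart_rate = 75)
scene <- simulate_scene(tree, flow, frame_rate = 25, duration = 10,
                        concentration = 3.82e7, seed = 11)
scene
#> Simulated ULM scene: 703 detections over 250 frames at 25 Hz
#>   31 ground-truth bubbles, 685 true consecutive-frame pairs
#>   flow: mean 3 mm/s, peak accel 112.5 mm/s^2; sigma_loc 10 um

fit <- mb_track(scene$detections, config = kalman_config(25, model = "accel"))
fit
#> Microbubble tracks (accel motion model)
#>   31 tracks from 703 detections; 655 consecutive-frame links
#>   track length: median 19, max 57 frames
#>   speed: median 1.25 mm/s (IQR 0.74-4.82)

confusion(fit$pairs, scene)
#> Pairing confusion: TP 655, FP 0, FN 30
#>   TPR (precision over pairs): 1   FNR (miss rate): 0.0438
```

The confusion report counts consecutive-frame bubble pairs: 655 of the
links the tracker asserted connect the same ground-truth bubble (no false
links here), and 30 true pairs were missed, mostly at track births.  From a
fit, `accumulate_map(fit, "density")`, `"speed"` or `"gradient"` renders
super-resolution rasters (`plot()` displays them; `write_map()` stores
float TIFF plus a JSON sidecar), and `interpolation_study()` reruns the
single-vessel comparison of chord versus acceleration-based interpolation.

A thin command-line interface wraps the same functions:

```sh
inst/cli/ulmtrack simulate --kind branching --frame-rate 25 --acc 75 \
    --duration 10 --seed 7 --out scene/
inst/cli/ulmtrack track --in scene/localisations.csv --frame-rate 25 \
    --model accel --out tracks.csv
inst/cli/ulmtrack render --tracks tracks.csv --frame-rate 25 \
    --kind density --out map.tif
```

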