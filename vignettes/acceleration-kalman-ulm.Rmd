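---
title: "Acceleration-based Kalman tracking for ultrasound localisation microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acceleration-based Kalman tracking for ultrasound localisation microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ulmtrack)
```

## The problem

Ultrasound localisation microscopy (ULM) reconstructs microvasculature far
below the diffraction limit by localising individual microbubbles over
thousands of contrast-enhanced frames and linking those localisations into
tracks.  The linking step is where resolution is won or lost: at clinically
realistic frame rates (tens of Hz) a bubble moves a substantial fraction of
a vessel diameter between frames, and cardiac pulsatility makes its speed
swing several-fold within a cardiac cycle.  A tracker that assumes constant
velocity between frames mispredicts exactly where the flow is most dynamic
— during the systolic speed-up and in curved vessels — and either drops the
bubble or links it to a neighbour.

`ulmtrack` implements a Kalman tracking pipeline whose motion model carries
an explicit acceleration state, together with everything needed to exercise
and validate it on synthetic data: a three-frame initialisation of new
tracks, gated minimum-cost association, acceleration-based nonlinear
trajectory interpolation, super-resolution map rendering, a pulsatile
microvasculature simulator with ground-truth identities, and pairing /
interpolation / velocity metrics.

## Motion model and pairing cost

The per-bubble state is `S = [x, vx, ax, y, vy, ay]` (positions in um,
velocities in um/ms, which is numerically mm/s, accelerations in um/ms²).
Each axis propagates by the constant-acceleration block

```
[1  dt  dt²/2]
[0   1  dt   ]
[0   0  1    ]
```

with `dt` the frame interval in ms.  The process noise is the standard
discrete white-jerk model `Q = G G' σa²`, `G = [dt²/2, dt, 1]'`: the
acceleration state performs a random walk with per-frame standard deviation
`σa`, and position and velocity inherit the integrated effect.  The
constant-velocity baseline used for all comparisons zeroes the acceleration
coupling in the transition and in `Q` and pins the acceleration states at
zero; everything else (gates, association, initialisation, lifecycle) is
shared, so differences between the two trackers isolate the motion model.

A track-detection pair is scored by the reciprocal Gaussian likelihood of
the observed position under the predicted observation distribution:
`cost = 1 / N(z; H S_pred, H P_pred H' + R)` with `H` selecting `(x, y)`
and `R = σ_obs² I`.  Pairs whose squared Mahalanobis distance exceeds a
χ²(2 df) quantile (99% by default, 9.21) are forbidden before assignment;
for a fixed innovation covariance this is equivalent to capping the cost,
but is scale-free.  Frame-to-frame association then minimises the total
cost over one-to-one matchings with a shortest-augmenting-path (Hungarian)
solver; dummy padding lets tracks and detections stay unmatched, so the
solver maximises the number of gated matches and, among those, minimises
total cost.

After a matched update (Joseph-form covariance update, which keeps `P`
symmetric positive semi-definite through arbitrarily long cycles), an
unmatched track is terminated once its consecutive-miss count exceeds
`max_misses` (0 by default — the lifecycle is deliberately unforgiving,
because a coasting rule is a separate modelling decision we do not take
here).

## Three-frame initialisation

A newly appeared bubble has no velocity estimate, so candidate triplets of
detections across three consecutive frames are scored with the normalised
vector difference of the two steps, `‖L23 − L12‖ / (‖L23‖ + ‖L12‖)` — 0
for uniform straight motion, 1 for a reversal, `√2/2` for a right-angle
turn.  Candidates are gated by a maximum step length `v_max · dt`
(`v_max` 50 mm/s by default) and a cost cap (0.5, rejecting turns sharper
than about 60° between equal steps).  A conflict-free set of triplets is
selected: exactly (maximum cardinality, then minimum total cost, by a
bitmask dynamic programme) when every frame has at most six unmatched
detections — the common case, since only detections the 2-D association
left unmatched enter this stage — and greedily in ascending cost order
otherwise.  The axial three-index assignment problem is NP-hard in
general, which is why exactness is restricted to small instances; the test
suite verifies the exact solver against exhaustive enumeration.

The accepted triplet seeds the state: central differences give
`v_init = (L12 + L23) / (2 dt)` and `a_init = (L23 − L12) / dt²`.  For
constant-acceleration motion `v_init` is exactly the velocity at the
*middle* frame, so the package advances it by `a_init · dt` before
attaching the state at the third frame; with that correction the seeded
state is exact for noise-free constant-acceleration motion (the second
difference identity), and the first prediction of the acceleration model
is unbiased.  Omitting the advance would bias precisely the model under
study while leaving the baseline (whose `a_init` is zero) untouched.

One sign convention deserves a note: kinematics requires the *difference*
of the two steps in the acceleration seed; a same-sign variant
(`(L23 + L12)/dt²`) is dimensionally identical but is not the second
difference and does not reproduce constant-acceleration motion, so the
difference form is used.

## Nonlinear interpolation and maps

Between two linked localisations the bubble path is modelled as the
quadratic `p(t) = p1 + v1 t + a t²/2`, where `v1` is the Kalman posterior
velocity at the first frame and `a` is the unique acceleration that lands
the path exactly on the next localisation:
`a = 2 (p2 − p1 − v1 dt) / dt²`.  Endpoint exactness is constructive, so
consecutive segments of a track join continuously.  Points are emitted
uniformly in arc length (default spacing: half a map pixel), which makes
density accumulation independent of local speed — a fast bubble contributes
the same number of points per unit path length as a slow one.

Three map kinds share one accumulation path: `density` counts interpolated
points per pixel; `speed` averages the per-point speed `‖v1 + a t‖`
(mm/s); `gradient` averages the per-gap spatial speed gradient
`Δspeed / Δdistance`, reported in 1/s and attributed to the gap midpoint.
A per-time variant (`Δspeed / Δtime`, mm/s² — tangential acceleration) is
available by flag; the spatial form is the default because the map is read
as a property of a *place* in the vasculature, not of a moment.  Pixels
never traversed are `NA` in averaged maps, never silently 0.

## The simulator

The simulator is a first-class module: it defines the conditions under
which the tracker's claims are tested.

**Geometry.**  Vessel centrelines are seeded smooth random-curvature
curves.  The branching tree used for tracking benchmarks has two main
vessels, each splitting into three downstream children (eight segments,
roughly 24 mm of centreline in a ~5 × 3 mm field).  The single tortuous
vessel used for the interpolation study is ~14 mm long with curvature that
varies slowly (knots every ~4 mm) and is bounded away from zero (radius
2–5 mm), giving smooth S-shaped bends that persist over several frame
steps — at 30 mm/s and 15 Hz a step spans 2 mm of arc, so only curvature
at that scale or larger distinguishes a chord from a quadratic.  Curvature
radii well below the step length would be invisible to any interpolation
scheme and are not generated.

**Pulsatile flow.**  Speed follows a raised-cosine systolic pulse
`s(t) = s_base + A (½(1 − cos 2πt/T))^q` with period `T = 60/heart-rate`.
`A` and `q` are solved numerically so the time-mean equals the nominal
speed (3 mm/s) and the peak `|ds/dt|` equals the requested acceleration
setting (0, 37.5, 75 or 112.5 mm/s²), with the baseline floored at 20% of
the mean.  A plain sinusoid cannot represent the strongest setting: at
75 bpm around a 3 mm/s mean it would require negative speeds, so the pulse
must sharpen (`q` grows) as the acceleration setting rises.  Bubbles
advance along their route by the time integral of this law, evaluated on a
0.5 ms grid (trapezoid rule; step-length error well under 0.1%).

**Arrivals and concentration.**  Bubbles enter at vessel inlets as a
Poisson process.  The expected number of concurrently present bubbles is
`concentration × lumen volume × detectable_fraction`, with a cylindrical
lumen of 50 um diameter.  The `detectable_fraction` (default 2 × 10⁻³)
represents the fraction of circulating bubbles isolated enough to be
localised in any one frame: at the study concentrations
(2.5–6.4 × 10⁷ MB/mL) the raw product would put thousands of bubbles in a
few centimetres of vessel — a contiguous column of gas that no
localisation scheme could resolve into points.  ULM works precisely
because only sparse, well-separated bubbles are localised; the factor is a
fixed generator constant, and since it multiplies all three concentration
settings equally it preserves the ordering that the concentration-trend
comparisons use.

**Resolvability.**  For the same reason, two bubbles closer than
`min_separation` (default 150 um — the half-wavelength diffraction scale
of a 5 MHz transmit) in the same frame are not emitted as separate
localisations: their echoes overlap within the point spread function and
isolated-bubble localisation rejects the pair.  Ground-truth pairs are
computed on the emitted detections, so the pairing metrics keep their
definitions.

**Noise.**  Localisations are jittered with isotropic Gaussian noise
(σ = 10 um by default), so the radial error is Rayleigh with mean
`σ√(π/2)` — a property the test suite checks to 5% over ≥1000 detections.
Missed detections and clutter are available (off by default) for
robustness experiments.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: no acoustic field or speckle is synthesised, no
point-spread-function image formation, no tissue motion or clutter
filtering residue, no depth-dependent localisation precision, and bubble
speed is a pure function of time, not of vessel diameter or branching
generation.  Conclusions about trends (model A vs model B under identical
conditions) transfer more credibly than absolute error magnitudes.

## Tracker parameters

* `sigma_a` (process noise, mm/s²; default 25).  The central filter-design
  trade-off.  Large values inflate the predicted-position covariance by
  `σa dt²/2` — hundreds of um per frame at 15 Hz — which flattens the
  pairing likelihood until nearby bubbles become interchangeable; small
  values shrink the gate below the transient prediction error of a
  systolic pulse, so tracks fragment.  The default was calibrated on
  simulated pulsatile scenes across 25–100 mm/s²: at 25 the acceleration
  model holds its tracks through the pulse (it predicts the transient)
  while the gate stays tight enough to keep neighbouring bubbles
  distinguishable.  Both motion models always share the value, so the
  comparison never hinges on asymmetric tuning.  For the single-vessel
  interpolation study the dynamics differ — 30 mm/s on bends of 2–5 mm
  radius implies centripetal accelerations `v²/R` of 200–450 mm/s² — so
  `interpolation_study()` uses a dynamics-matched 300 mm/s² (one bubble is
  present at a time, so the wider gate costs nothing).
* `sigma_obs` (um; default 10) matches the simulator's localisation noise
  and sets `R = σ_obs² I`.
* `gate_chi2` (default `qchisq(0.99, 2)` ≈ 9.21): the association gate.
* `p0_diag`: initial covariance per axis
  `[s², (2s/dt)², (4s/dt²)²]` with `s = max(σ_obs, 1)` — localisation
  noise propagated through first and second differences.
* `v_max` (50 mm/s) and `cost_cap` (0.5): initialisation gates.
* `max_misses` (0) and `min_track_length` (3): lifecycle.

## Numerical choices

Internal units are um and ms throughout, so mm/s and um/ms coincide and
unit bugs surface as factor-1000 errors immediately.  The Kalman update
uses the Joseph form.  The innovation covariance is inverted analytically
(2 × 2).  Assignment uses potentials-based shortest augmenting paths on a
dummy-padded square matrix; forbidden pairs carry a large finite sentinel
chosen so they are never profitable.  Ties in assignment and triplet
selection resolve deterministically by scan order, and the tracker contains
no randomness, so identical inputs give byte-identical outputs.
Interpolation parameterises arc length on a fine auxiliary grid (at least
eight sub-steps per emitted point) and inverts it by linear interpolation;
endpoints are emitted at exactly `t = 0` and `t = dt`.  Stationary
triplets (both steps below 1 nm) are assigned cost 0 and zero velocity
rather than the undefined 0/0.  Ratios with empty denominators (TPR with
no produced pairs, FNR with no truth pairs) are reported as `NA`, never 0
or 1.

## Problem sizes in the shipped checks

The full study grid (10 trees × 3 frame rates × 3 concentrations × 4
accelerations = 360 scenes of 30 s) is enumerated exactly but executed
only at reduced scale in the automated checks: the tracking-trend
comparison runs 10 tree replicates × 3 frame rates at the middle
concentration and the strongest pulsatility for 10 s per scene, for both
motion models; the interpolation study runs six vessels × 3 frame rates at
20–30 s per scene.  These sizes are the package's own choice of a
representative, repeatable experiment; `run_benchmark()` accepts the full
grid for users who want the complete sweep.

## Known limitations

Association is strictly frame-to-frame with a 3-frame birth window; there
is no deferred (multi-hypothesis or MCMC) data association, no coasting by
default, and no multi-feature costs (intensity or shape).  The
acceleration model is linear-Gaussian; a constant-turn-rate model with an
unscented filter is a different design and out of scope.  The speed
gradient is reported along the direction of travel only.  FRC resolution
estimation uses a deterministic alternate split of tracks, which slightly
correlates the two half-reconstructions when tracks are long.  None of
the in vivo preprocessing chain (registration, tissue filtering,
PSF-correlation localisation) is included: the package starts from
localisation tables.
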