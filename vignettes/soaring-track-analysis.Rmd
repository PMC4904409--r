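---
title: "Segmenting and scoring soaring-gliding flight from 1-Hz GPS/ACC tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting and scoring soaring-gliding flight from 1-Hz GPS/ACC tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soarseg)
```

Large soaring birds such as griffon vultures cover their foraging range
almost for free: they circle upward in thermals (rising columns of warm
air), then glide toward the next thermal, losing the height they just
gained. At a 1-s GPS fix rate this behaviour is directly visible in the
track, and with a gridded atmospheric reanalysis alongside it one can ask
quantitative questions about *flight skill*: how fast does a bird climb,
how tightly does it circle, how does it place itself within a
wind-drifted thermal, how boldly does it choose its gliding airspeed, and
how much does all of this cost energetically. `soarseg` implements that
analysis chain end to end, together with a synthetic track generator that
provides exact ground truth for validating every stage.

## The segmentation model

Flight is first separated from non-flight by the conventional
ground-speed threshold (2 m/s), with a 3-fix majority filter removing
1-s blips. Within contiguous 1-Hz flight stretches, two rules partition
the track:

1. **Thermal soaring** is detected *geometrically*: circling produces
   self-intersections of the 2-D path (altitude ignored). Every step
   segment is tested for proper intersection against the preceding 120 s
   of steps; crossings chain into candidate events, events within 10 s of
   each other merge, and an event qualifies as a thermal if it lasts more
   than 45 s with a positive net altitude change.

   A closed loop is evidence of circling that *began up to one circle
   earlier*, and the final partial circle never closes, so crossing spans
   alone systematically miss the head and tail of each climb. Event
   boundaries are therefore snapped to the maximal contiguous arc of
   consistent signed turning containing the crossings. The turn-rate
   series is averaged over 3 s before thresholding (8 deg/s minimum, with
   2 s of patience) because GPS jitter produces spurious per-step turning
   of several deg/s, while genuine circling at a 20-s period turns at
   18 deg/s; the 3-point average widens a suprathreshold arc by exactly
   one step per side, which the index conversion compensates.

2. **Gliding and linear soaring** are detected from the *vertical-speed
   trend* outside thermals: maximal runs in which at least 90% of
   smoothed vertical-speed samples share a sign (negative = glide,
   positive = linear soaring, i.e. straight climbs in orographic lift).
   Samples with exactly zero smoothed vertical speed count toward neither
   trend. The scanner closes a candidate at the last position where the
   in-trend fraction still met the threshold once the consecutive
   off-trend run exceeds 5 s, and re-scans the remainder. Edges are then
   trimmed greedily: remove the first or last sample - whichever raises
   the in-trend fraction more - while any single-sample removal strictly
   increases it. Runs shorter than 10 s are discarded.

Two conservative post-passes stabilise boundaries: same-mode runs split
by a short noise burst re-merge across gaps of up to 10 s of contiguous
flight, and unassigned transition gaps of up to 5 s between a thermal and
a trend segment - created because the 5-s smoothing window mixes both
modes across the boundary - are assigned fix-by-fix using the sign of the
*raw* vertical speed (still-climbing fixes extend the thermal, sinking
fixes the glide). Thermal boundaries set by the circling arc are never
moved otherwise.

Vertical speed itself is the first difference of altitude above ground
over elapsed time, smoothed over a centred 5-s window by locally weighted
linear regression with tricube distance weights and two bisquare
robustness iterations - the classical robust-lowess construction, with the
robustness weights computed per point from the stretch-wide residual
distribution so that a single altitude spike (which contaminates the
difference series with *two* opposite outliers) is fully rejected.
Windows truncate at stretch edges and never bridge gaps longer than 2 s.
Smoothing operates on the difference series, not on altitude; the two
orders differ only at mode boundaries and the difference series is the
quantity the trend rule consumes.

## Wind, airspeed and circling geometry

Wind comes from a 4-D grid (1-km horizontal, 5-min temporal resolution;
U, V and turbulent kinetic energy) interpolated multilinearly in x, y,
altitude and time. Spatial edge queries clamp (and are counted); temporal
extrapolation is refused. From the interpolated wind vector:

* **airspeed vector** = ground velocity - wind; **wind support** is the
  wind component along the direction of travel and **side-wind** the
  perpendicular component, signed positive when the wind comes from the
  bird's left (the decomposition is exactly orthogonal, so
  support^2 + side^2 = |wind|^2). Wind support and side-wind are reported
  for gliding segments only.
* **wind shear** of a thermal is operationalised as the mean horizontal
  wind speed along it - the drift a circling bird must compensate - binned
  into low (< 2), intermediate (2-6) and strong (> 6 m/s) classes. The
  middle interval is closed on both ends, a boundary decision the
  interval notation leaves open.
* the **flight-versus-wind angle** is the circular difference between
  heading and the direction the wind comes from: 0 = headwind, +/-180 =
  tailwind, positive = wind from the left, so clockwise and
  counter-clockwise circling remain separable.
* the **lee/windward partition** projects each drift-compensated fix onto
  the wind axis through the drift-compensated circle centre; the downwind
  half of the column is the lee side. A positional rule was preferred
  over the flight-angle proxy because it remains valid when the bird's
  circling is eccentric about the core; with calm wind the partition is
  withheld.

**Circling radius** subtracts the integrated interpolated wind (the
drift) from the projected positions, splits the event into full 360-deg
loops by cumulative turning, fits a circle to each loop by algebraic
least squares (the Kasa fit) with one Gauss-Newton refinement step, and
averages per-loop radii. On a noise-free helix the estimate is exact to
numerical precision regardless of uniform drift; at a 3-m GPS error the
mean over 100 thermals is within a few tenths of a metre of truth.

## Airspeed choice, efficiency and energetics

The glide polar is a declared input: sink(v) = a v^2 + b v + c over a
valid range, defaulting to a large soaring bird with best-glide speed
`r round(best_glide_speed(glide_polar()), 1)` m/s. The best-glide speed
maximises v / sink(v) (closed form sqrt(c/a)); the MacCready speed for an
expected climb rate maximises cross-country speed (closed form
sqrt((c + climb)/a)). The **Risk-Averse Flight Index (RAFI)** locates the
observed gliding airspeed between the two reference speeds:
(V_mc - V_obs) / (V_mc - V_bg), clipped to [0, 1.2], so 1 means gliding
at the risk-averse best-glide speed and 0 at the risk-prone MacCready
speed. The index is sometimes verbally described as a ratio of actual to
theoretical risk-averse airspeed; both readings are implemented
(`rafi.definition` = "normalized" or "ratio") and the normalized form is
the default - the two are not silently reconciled because they disagree
about direction.

**Soaring-gliding efficiency** is the glide's travel distance divided by
the duration of the thermal that precedes it (pairing gap at most 10 s),
in metres of glide per second of climb; daily values average over pairs.
**ODBA** (overall dynamic body acceleration) removes the per-axis burst
mean as the static component - bursts are only 3.8 s, too short for
within-burst drift - and averages the summed absolute dynamic
acceleration. Flapping is classified by a transparent two-feature rule
standing in for a field-trained supervised classifier: ODBA above 0.6 g
*and* at least half of the heave-axis spectral power inside the 3-5 Hz
wingbeat band. The thresholds were calibrated once against synthetic
fixtures, where they separate the classes completely, and are frozen in
the configuration; they are not a field calibration.

Daily path metrics are the travel distance (sum of between-sample
distances), the maximum displacement from the day's first fix, and the
straightness index - maximum displacement divided by the travel distance
accumulated *up to* the fix of maximum displacement, so a straight
out-and-back day still scores 1. Foraging days are those with travel
distance <= 200 km, straightness <= 0.7 and distance from the main roost
<= 60 km; the roost threshold is not dictated by the segmentation model
and is config-exposed.

## The inferential layer

Group comparisons (e.g. adult vs juvenile) use Mann-Whitney-Wilcoxon
tests on per-individual means - the conservative unit of analysis for
small samples of birds - via `stats::wilcox.test` (exact when n1 x n2 <=
400 without ties). The effect of group on circling radius given wind
shear is a Type-II ANCOVA (`response ~ group + shear`). Per-thermal climb
rates are binned by wind shear (1-m/s bins; bins missing a class are
dropped) and the group difference per bin is fitted with three nested
models - constant, linear and quadratic ("hump-shaped") - compared by the
small-sample Akaike criterion

AICc = n ln(RSS/n) + 2k + 2k(k+1)/(n-k-1),

with k counting all regression coefficients including the intercept
(the Gaussian variance term is shared across the candidates and drops
out of the comparison), and adjusted R^2 = 1 - (1-R^2)(n-1)/(n-k). The
per-model p-value reported in the comparison table is the F test of the
full regression, a package convention. One practical note: with only ~9
bins the k = 3 penalty is severe, and a quadratic signal whose noise is
25% of its range is picked in well under 90% of replicates no matter how
AICc is computed; the package's model-selection property tests therefore
use 20 synthetic bins, where the stated selection rates hold.

## What the synthetic generator emulates - and what it does not

`simulate_track()` builds bird-days in a local planar frame (converted to
lon/lat through an exact spherical azimuthal-equidistant projection):
circling climbs as helices of configured radius and period whose centres
are advected by the altitude-interpolated wind, ascending at
updraft - sink; straight glides at configured airspeed plus wind ending
after a configured ground distance; occasional straight linear-soaring
climbs; 600-s roost fixes around the flight; ACC bursts every 60 s with
flapping bursts injected at a configured probability as a 4-Hz, 1-g
heave-axis sinusoid over body-motion noise. GPS noise is added last.

Defaults are *calibrated to the published summary statistics for foraging
griffon vultures* - thermal duration 150 s, climb 1.4 m/s (updraft 2.15
minus sink 0.75), glide sink 0.75 m/s, circling radius 35.9 m, glide legs
900 m (so the true soaring-gliding efficiency is 900/150 = 6), flapping
probability 0.02, a desert daytime wind profile rising from 1 to 5 m/s
over the lowest 2 km. These are calibrations, not measurements: the
spread parameters (updraft sd 0.3 m/s, duration sd 30 s) are chosen as
plausible, and the default gliding airspeed (15.8 m/s) sits between the
default polar's best-glide and MacCready speeds so that RAFI is
informative. The efficiency-recovery scenario uses 9.5 m/s instead,
giving ~95-s glide legs closer to published glide durations.

GPS error is Gaussian AR(1) with a 20-s correlation time and a 3-m
marginal standard deviation. The autocorrelation is essential realism,
not a convenience: receiver filtering makes 1-Hz position errors strongly
correlated, and *white* 3-m errors would imply ~4 m/s vertical-speed
noise between consecutive fixes - an artefact no 1-Hz flight dataset
shows, and one that would defeat any sign-based trend rule, including the
one real tracks are analysed with. Setting `gps_noise_rho = 0` recovers
white noise for stress tests.

The generator deliberately omits: thermal life cycles and spatial
structure (updraft is uniform across the column unless the lee-side bias
knob is set), terrain (altitude is above flat ground), gradual
transitions between modes, airspeed variation within a glide, and any
behavioural decision-making. Passing recovery tests on these tracks
therefore demonstrates that the *algorithms* recover what they claim
under controlled conditions - clean mode geometry with realistic noise -
not that every real track will segment as cleanly; real thermals with
weak circling, strong turbulence or mixed modes will be harder.

## Numerical choices and degenerate inputs

* Segment durations follow the half-open convention: a segment covering
  fixes [i0, i1] lasts i1 - i0 + 1 s at the 1-Hz cadence, and the mean
  vertical speed is defined as altitudinal change over that duration, so
  climb rate and segment characterisation agree exactly.
* Self-intersection uses the strict proper-crossing predicate; collinear
  touching does not count. The 120-s lookback bounds cost at O(n x w)
  and cannot miss circling at 15-25-s periods.
* The Kasa circle fit falls back to `NA` for degenerate loops (fewer
  than 3 points, or a non-positive discriminant); thermals with less
  than one full loop have no radius.
* Calm wind (< 0.1 m/s) makes the flight-versus-wind angle and the
  lee/windward partition undefined; they are withheld, not zeroed.
* A zero robust scale in the smoother (the majority fitting exactly)
  rejects any point with a nonzero residual instead of reinstating
  outliers.
* Ties in the greedy edge trim go to removing the first sample.
* Zero RSS in model fitting yields AICc = -Inf, correctly selecting the
  exactly-fitting model.

## Problem sizes used in validation

The test-suite and the acceptance script validate at a desk scale chosen
to keep the whole suite fast while leaving estimator standard errors well
inside the tolerances: 20 simulated bird-days (~200 thermals, ~50,000
fixes) for segmentation and climb/sink recovery, 20 days for efficiency,
30 days for flapping proportion, and 100 thermals for the circling
radius. At these sizes the full pipeline runs in seconds per scenario.

## Known limitations

* The flapping classifier is a synthetic-fixture stand-in; applying it
  to real accelerometry requires recalibrating its two thresholds
  against field-validated labels.
* Thermal detection assumes circling; a bird climbing in a thermal
  without looping (strong drift, slope soaring) is labelled linear
  soaring by design, mirroring the two-stage rule it implements.
* The altitude datum is the caller's responsibility: the track schema
  requires altitude *above ground*; no ellipsoid/geoid/terrain handling
  is performed.
* Wind grids are trusted as given; no attempt is made to reconstruct
  thermal updraft fields from the track itself.
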