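---
title: "From marker trajectories to muscle architectural gear ratios"
author: "chewgear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From marker trajectories to muscle architectural gear ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chewgear)
```

## The measurement problem

Marker-based biplanar videoradiography (the XROMM workflow) records the 3D
positions of radiopaque beads implanted in the cranium, the mandible, and a
jaw-elevator muscle while an animal chews. From those trajectories one wants
per-frame estimates of:

* **gape distance** — displacement of an anterior mandibular marker from
  its position at maximum occlusion;
* **fascicle length** `l(t)` — distance between a bead at the central
  myotendinous junction (CMJ, `m1`) and one at the fascicle's superficial
  termination (`m2`);
* **whole-muscle length** `L(t)` — distance from the coronoid-process tip
  (a CT landmark animated by the mandibular rigid-body transform) to the
  superior-attachment bead (`m3`);
* **planar fascicle (pinnation) angles** — the angle between the fascicle
  vector `m2 - m1` and the muscle-line vector `m3 - m1`, projected into the
  sagittal and the coronal plane and folded into [0°, 90°];
* the **architectural gear ratio** `AGR = (dL/dt) / (dl/dt)` — whole-muscle
  velocity over fascicle velocity. `AGR > 1` means fascicle rotation
  amplifies muscle velocity; `AGR < 1` means a configuration favoring force.

The pipeline (`run_pipeline()`) composes the stages in a fixed order: gap
interpolation, zero-phase low-pass filtering, cranial-frame fixing,
mandibular rigid-body registration, landmark animation, gape distance,
cycle segmentation with phase detection, per-frame architectural variables
and velocities (in real time), standardization of each cycle to 50 frames
(0–100 % of cycle), per-food averaging, LOESS smoothing of the averaged
velocities, and finally the AGR with its validity mask.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `frame_rate` | 150 | frames/s | recording rate of the videoradiographs |
| `filter_cutoff_hz` | 30 | Hz | low-pass cutoff for marker coordinates |
| `filter_order` | 4 | — | Butterworth order (zero-phase two-pass) |
| `n_standard` | 50 | frames | standardized cycle length |
| `loess_span` | 0.25 | — | LOESS span for averaged velocity curves |
| `agr_epsilon_frac` | 0.02 | — | AGR mask threshold, fraction of peak fascicle speed |
| `min_prominence_frac` | 0.2 | — | gape-maximum prominence to count as a cycle boundary |
| `max_gap_frames` | 5 | frames | longest occlusion gap bridged by linear interpolation |

The filter order and its two-pass (forward–backward) application are
choices of this package: the two passes cancel phase lag exactly, which
matters because phase-transition *timing* is read off derivatives of the
filtered gape. Each pass pads the series with `3 x order` odd-reflected
samples and subtracts the leading value, so a constant series passes
through unchanged and edge transients stay confined to the padding.
Filtering is applied to each marker coordinate independently, after gap
interpolation and before registration.

## Registration and coordinate systems

Rigid-body fits use the Kabsch/SVD solution to the least-squares
rotation-plus-translation problem, with the reflection case corrected so
`det(R) = +1`. Two registrations run per frame:

1. **Cranial fixing** maps every frame's cranial-marker configuration onto
   a reference configuration, making the cranium stationary. If the
   cranial marker coordinates from the CT scan are supplied
   (`cranial_reference`), the output lives directly in CT/anatomical
   coordinates; otherwise the first complete frame is used.
2. **Mandibular transforms** map the mandibular reference configuration
   onto each frame. When the CT marker configuration is supplied
   (`mandibular_reference`) the transforms carry CT landmarks — the
   coronoid tip in particular — on exactly the right material points.
   Without it, the occlusion frame serves as reference: it is the pose in
   which landmarks are defined, and it sits mid-recording, away from
   filter edge effects. (Using the first frame as reference is subtly
   wrong: the reference configuration is then taken inside the filter's
   edge transient, which displaces every transformed landmark by a small
   constant rigid error.)

The anatomical frame fixes the axes: sagittal plane = span(AP, SI),
coronal plane = span(ML, SI), right-handed with `AP x SI = ML`.

## Occlusion and gape

"Maximum occlusion" is found from the anterior mandibular marker alone.
The trajectory is scored along its first principal axis (dominated by gape
motion); of the two trajectory ends, the *superior* one is the closed jaw —
jaw depression lowers the anterior mandible, and this anatomical fact is a
more robust discriminator than dwell time, which depends on the phase
durations. Because the jaw retraces the same arc through occlusion, the
occlusion reference must be an arc *vertex*: we take the extreme of the
lightly smoothed score. Gape is then the Euclidean distance from the
marker's position at that frame, and is zero there by construction.

## Cycle segmentation and phase detection

A gape cycle runs between successive gape maxima whose topographic
prominence reaches 20 % of the recording's gape range (rejecting
within-chew jitter). Cycles with missing frames are dropped; cycles
touching the recording boundary cannot arise because boundaries must be
interior maxima.

Within a cycle, the four phases FC (fast close), SC (slow close), SO (slow
open), FO (fast open) are bounded by three events:

* **minimum gape** (the SC/SO transition): argmin of the lightly smoothed
  gape;
* **FC/SC**: the strongest abrupt *drop* in jaw acceleration during
  closing — jaw elevation braking as the teeth meet the food;
* **SO/FO**: the strongest abrupt *rise* in acceleration during opening.

Acceleration is the central second difference of gape, smoothed with a
5-frame moving average; the abrupt-change events are located as extrema of
its derivative. An earlier formulation used the arg-max of acceleration
itself; we found that the discrete arg-max sits structurally 1–2 frames
before the true junction (the acceleration ramps up to the junction and
then cliffs, and smoothing drags the maximum into the ramp), whereas the
derivative extremum of a step is unbiased under symmetric smoothing.
The search is restricted to a mid-gape band (8–60 % of the half-cycle's
gape excursion): the turning points at occlusion and at maximum gape carry
their own acceleration corners that are not phase transitions. Ties take
the earliest frame.

## Velocities, smoothing, AGR

Velocities are temporal derivatives of the length series — central
differences on interior frames, one-sided at the ends, in mm/s, shortening
negative. They are computed on the *real-time* series and standardized to
the 50-frame %cycle grid afterwards; standardizing first would distort
time and hence derivatives. Standardized cycles are averaged per food, the
averaged velocity curves are LOESS-smoothed (local linear, tricube
weights, 25 % span), and the AGR is their pointwise ratio.

The ratio is undefined near fascicle-velocity zero crossings (minimum and
maximum gape). Frames are masked unless the fascicle speed reaches
`agr_epsilon_frac` (2 %) of the cycle's peak fascicle speed *and* the two
velocities share sign; the masked fraction is reported with the result,
never silently dropped. Per-cycle AGR summaries (`cycle_agr_summary()`)
use the same machinery cycle by cycle and feed the statistics layer.

"Gape-controlled" comparisons are supported through two routes: gape
distance as a fixed covariate in the mixed model (the default route), or
residuals from a pooled linear regression of the variable on gape within
the jaw-closing and jaw-opening halves separately
(`gape_control_residuals()`).

## The statistics layer

`fit_lme()` fits `response ~ fixed + (1 | subject) + (1 | subject:food) +
(1 | subject:food:cycle)` by maximum likelihood (lme4), the random
intercepts encoding gape-cycle order nested in food nested in subject.
Random slopes are not fitted: the nesting statement specifies grouping
only. When the response is a per-cycle summary, the cycle-level intercept
is inseparable from the residual and is dropped (reported as 0). Term
significance uses Type-II Wald chi-square tests; marginal and conditional
R² are computed in-package from the variance of the fixed-effect
predictor, the summed random-intercept variances, and the residual
variance (the standard variance-partition formulation for mixed models).
"Sequential Bonferroni" is implemented as Holm's step-down procedure — the
standard referent of that term — via `stats::p.adjust`. Reduced major axis
regression uses its closed form, slope `sign(r)·sd(y)/sd(x)`. The paired
timing comparison (`event_timing_offset()`) reports offsets as % of cycle
with a two-sided one-sample t-test; the original analysis does not name
its test, so this choice is flagged here.

## What the synthetic generator emulates — and what it does not

`synthetic_scenario()` + `simulate_recording()` build a complete recording
with known truth: 4 cranial + 4 mandibular + 3 muscle markers at 150
frames/s, a C¹ piecewise-cosine gape trajectory with four phases of
configurable duration, a mandible rotating about a mediolateral axis
through a condyle-adjacent center (the chord relation
`2 r sin(phi/2) = gape` makes the anterior marker's displacement equal the
prescribed gape exactly), optional slow rigid head drift, and Gaussian
marker noise with SD defaulting to 0.15 mm — the midpoint of the reported
0.1–0.2 mm spatial precision of the technique.

The fascicle geometry gives the AGR in closed form. With the muscle belly
`b(t) = L(t) - L_tendon` and transmission factor `k` (default 1,
inextensible tendon):

* **constant pinnation** (`theta = theta0`): `l = k·b/cos(theta0)`, so
  `AGR = cos(theta0)/k < 1` — the reduced-rotation, force-favoring limit;
* **constant thickness** (`l·sin(theta) = t0`):
  `l = sqrt(k²b² + t0²)`, `theta = atan2(t0, k·b)`, so
  `AGR = 1/(k·cos(theta)) > 1` — the fascicle-rotation,
  velocity-amplifying limit;
* **prescribed theta(gape)** for arbitrary trajectories (truth AGR by fine
  finite differences).

Generator design choices worth knowing:

* Phase junctions sit at 20 % of the cycle's gape amplitude (tooth–food
  contact at moderate gape). This keeps the junction acceleration steps
  dominant while the occlusal minimum stays sharply curved enough to
  localize under noise.
* Default phase durations (12, 13, 13, 12 frames ≈ 0.33 s cycles) are in
  the range of observed primate chew cycles; the validation grid varies
  the fast:slow ratio from 1:1:1:1 to 3:1:3:1 at constant total duration,
  consistent with the reported near-constancy of cycle duration across
  foods.
* The CMJ marker rides the central tendon at 75 % of the muscle belly from
  the superior attachment — the CMJ lies near the deep/tendon end, which
  also gives the muscle-line reference vector a realistic 8–12 mm length.
* The fascicle plane is sagittal by default; a coronal tilt of 26° (found
  by a one-time noiseless sweep) reproduces the pattern in which the
  sagittal angle varies about twice as much as the coronal angle over the
  gape cycle.
* `make_study()` assembles 3 subjects × 5 foods; the two mechanically
  challenging foods are generated in constant-pinnation (low-AGR) mode and
  the three compliant foods in constant-thickness (high-AGR) mode, so the
  food-material-property contrast is recoverable end to end.
  `null_effect = TRUE` removes the contrast exactly for type-I checks.

What the generator does **not** emulate: soft-tissue artifact (markers are
ideal material points), marker occlusion dropouts (missingness can be
injected but has no soft-tissue correlation structure), non-rigid cranial
deformation, tendon compliance dynamics (only the static `k` factor),
muscle activation, and food-bolus mechanics. Passing the validation suite
therefore shows the *estimator chain* is correct and noise-robust at the
stated precision — not that in-vivo recordings are free of these further
effects.

## Numerical choices and degenerate inputs

* Ties in any argmin/argmax take the earliest frame.
* Cycles shorter than 8 frames are rejected by `detect_phases()`.
* Planar angles mask frames whose projection norm falls below 1e-9 mm;
  coincident fascicle markers give length 0 with a degeneracy warning.
* Occlusion gaps longer than 5 frames stay missing; observed runs too
  short to filter (≤ `3 x order` samples) also become missing; cycles
  containing missing frames are dropped.
* The AGR mask, not a numerical epsilon in the division, handles the
  velocity zero crossings.
* Validation problem sizes: 5-cycle recordings for the analytic-limit and
  pattern checks, 3 × 6-seed noisy grids for phase recovery, 500
  replicates for mixed-model coverage and type-I calibration, 1000 random
  transforms for the registration oracle.

## Known limitations

* Phase detection assumes one prominent gape minimum per cycle; double
  bites within one nominal cycle will confuse the band-limited search.
* The per-frame sagittal-angle noise floor at 0.15 mm precision is ~1.2°
  with this marker geometry; per-frame angle series should be interpreted
  through the averaged curves, which is how the pipeline reports them.
* With three subjects, mixed-model variance components at the subject
  level are poorly determined (singular fits are common and flagged); the
  fixed-effect inference is what the calibration checks validate.
* The pipeline's per-food AGR follows the source workflow (average, then
  smooth, then ratio); per-cycle AGR summaries are provided but are the
  package's own extension.
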