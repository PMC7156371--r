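# chewgear

Jaw kinematics and dynamic muscle architecture from marker-based
videoradiography.

`chewgear` is for researchers who record chewing with marker-based
biplanar videoradiography (the XROMM workflow) and want per-gape-cycle
estimates of how a jaw-elevator muscle changes shape while it works: the
package turns XMALab-style 3D marker trajectories plus CT-derived
landmarks into gape distance, gape-cycle phases, fascicle and whole-muscle
lengths, planar pinnation angles, velocities, and the **architectural gear
ratio (AGR)** — whole-muscle velocity divided by fascicle velocity,

```
AGR(t) = (dL/dt) / (dl/dt)
```

with `L(t)` the coronoid-tip-to-superior-attachment muscle length and
`l(t)` the fascicle length between the central myotendinous junction and
the fascicle's superficial termination. `AGR > 1` means fascicle rotation
amplifies muscle velocity; `AGR < 1` is the reduced-rotation configuration
that favors force — e.g. when chewing mechanically challenging foods.

The processing chain is the field-standard one: zero-phase 30 Hz
Butterworth filtering of marker coordinates; cranial-frame fixing and
per-frame mandibular rigid-body transforms by Kabsch/SVD registration;
gape cycles as max-gape-to-max-gape spans; the FC/SC, SC/SO and SO/FO
phase transitions from instantaneous changes in jaw acceleration (second
derivative of gape); cycle standardization to 50 frames; per-food
averaging; 25 %-span LOESS smoothing of velocity curves before the AGR.
The statistics layer fits the matching nested mixed models (cycle within
food within subject, ML) with marginal/conditional R², Holm ("sequential
Bonferroni") adjustment, reduced-major-axis scaling and paired
event-timing tests.

Because in-vivo recordings are large and external, the package ships a
first-class synthetic generator: a rotating rigid jaw plus a pinnate
fascicle whose length, pinnation angle and AGR are known in closed form
(`AGR = cos(theta0)` for constant pinnation, `1/cos(theta(t))` for
constant muscle thickness), with the study's recording characteristics —
150 frames/s, 4+4+3 markers, 0.1–0.2 mm marker precision, four-phase gape
cycles. Every stage of the pipeline is validated against this analytic
ground truth.

## Worked example

Simulate one noisy recording with known truth, run the full pipeline, and
compare:

```r
library(chewgear)

scen <- synthetic_scenario(mode = "constant_thickness", theta0_deg = 20,
                           n_cycles = 5, noise_sigma = 0.15, seed = 1)
rec <- simulate_recording(scen)
res <- run_pipeline(rec$config, rec$dataset, rec$landmarks)
res
#> <chew_pipeline_result> subject subject1, food food1: 5 gape cycles
#>   AGR defined on 98% of the standardized cycle (mask fraction 0.02)

res$cycle_table[, c("cycle_index", "start_frame", "fc_sc", "min_gape",
                    "so_fo", "end_frame", "duration_s")]
#>   cycle_index start_frame fc_sc min_gape so_fo end_frame duration_s
#> 1           1          27    38       50    63        76  0.3266667
#> 2           2          76    87      101   113       126  0.3333333
#> 3           3         126   139      151   164       177  0.3400000
#> 4           4         177   188      201   213       226  0.3266667
#> 5           5         226   238      254   262       276  0.3333333
```

Each row is one gape cycle (max gape to max gape, ~0.33 s at 150
frames/s) with the detected FC/SC, minimum-gape (SC/SO) and SO/FO
transition frames. The recovered architecture matches the generator's
closed-form truth despite the 0.15 mm marker noise:

```r
fa <- res$food_average
median(fa$agr, na.rm = TRUE)
#> [1] 1.030      # ground-truth AGR spans 1.026 - 1.064 over the cycle
range(fa$sagittal_angle)
#> [1] 13.1 20.4  # true pinnation angle spans 12.8 - 20.0 deg
```

An AGR above 1 is exactly what the constant-thickness (fascicle-rotation)
mode should produce. A full simulated feeding study — 3 subjects × 5
foods, with the mechanically challenging foods built in the low-AGR
constant-pinnation mode — and its mixed-model test of the food effect:

```r
st <- make_study(n_cycles = 10, seed = 7)
out <- study_fmp_test(st)
out$p_fmp                      # food-material-properties effect on AGR
tapply(out$agr_table$agr_median, out$agr_table$fmp, median)
#>  high   low
#> 0.925 1.047
```

A thin command-line wrapper lives at `inst/scripts/chewgear-cli.R`
(`process` for real CSV/YAML inputs, `simulate` to write fixture sets).

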