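---
title: "Quantifying ascending ant trajectories: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ascending ant trajectories: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antnav)
```

# The measurement problem

A foraging bull ant climbing its nest tree is videotaped at 25 frames
per second inside a marked recording window (by default 70 cm wide and
1 m high, starting 50 cm up the trunk). Point-tracking yields two
coordinates per frame: the tip of the head and the centre of the
thorax. From nothing more than those two streams, the pipeline must
answer: how fast and how straight did the ant travel, how often did it
stop to scan its surroundings, and — when an odour strip lies across
the corridor — did it walk over the strip, go around it, or abandon the
ascent?

All coordinates are arena-frame millimetres with +y pointing up the
trunk; angles are degrees, counterclockwise from +x, wrapped to
(−180°, 180°] (internally radians). Pixel-to-millimetre calibration is
the caller's responsibility (`read_trajectory(scale = )` applies a
single factor); the stop threshold below presumes millimetre units.

# Kinematics

A **step** is the thorax displacement between consecutive frames; a
**turning angle** is the wrapped change of direction between
consecutive steps. Zero-length steps have no direction, so their
heading is undefined and turning-angle pairs touching them are skipped
and counted rather than fabricated as zero — while the ant is
stationary there is no meaningful travel direction, and the stop filter
already isolates those frames.

**Speed** is step length over frame interval. Frames in stop episodes
(steps with speed below `v_stop`) are excluded from *both* the distance
and the time entering the mean, so long waits cannot dilute the
walking speed; a trajectory with no moving step reports an undefined
mean with an explicit flag rather than zero. The default
`v_stop = 0.01` mm/s is retained as the conventional threshold for
this assay even though it is far below the displacement noise of
25 fps tracking; it is configurable and always logged, and with clean
synthetic data it cleanly separates implanted stops (exactly zero
displacement) from walking.

**Orientation** is the direction of the line from thorax through head,
per frame; frames with coincident points are undefined (counted, never
interpolated). **Orientation angular velocity** is the wrapped
orientation change over the frame interval; since the ants' heads
oscillate left-right as they walk, the headline summary is the mean
*magnitude* (the signed mean is reported alongside and is ≈ 0 for a
symmetric sweep).

No coordinate smoothing is applied by default: metrics are defined on
the raw digitised points, and any filtering would bias step lengths and
turning angles downward in a resolution-dependent way.

# Path straightness

Two indices summarise meander, computed from the per-trajectory sample
quantities `p` (mean step length), `c` (mean cosine of turning angles)
and `b` (step-length coefficient of variation):

$$S = 2\left[p\left(\frac{1+c}{1-c} + b^2\right)\right]^{-1/2},
\qquad
E^{a}_{max} = \frac{\beta}{1-\beta},\ \beta = c .$$

Higher sinuosity means a more convoluted path (units mm^−1/2 on
millimetre steps); higher maximum expected displacement means a
straighter one (dimensionless, units of steps — the asymptotic expected
displacement of a correlated random walk with that turning
concentration). Choices worth stating:

- `b` uses the population-style CV (denominator *n*); the sample-style
  (*n* − 1) form is switchable. At trajectory lengths of hundreds of
  steps the difference is far below sampling noise.
- `c` and `β` are the same sample quantity, computed once.
- Steps are taken at the native frame interval; no rediscretisation to
  constant step length is applied, keeping the estimate tied to the
  recorded data.
- Degenerate geometry is flagged, not fatal: an effectively straight
  path (c within 1e−9 of 1) returns S = 0 with a
  `degenerate_straight` flag and an infinite `e_a_max` with a
  `straight` flag, so batch tables never abort.
- Only the asymptotic `β/(1−β)` is reported; no finite-*n* correction
  is applied, so very short trajectories read slightly straight-biased.

**Trip duration** is wall-clock residence: time of the last frame
inside the arena minus the first, stops included — deliberately
distinct from the moving time inside the speed summary.

# Scanning bouts

A scanning bout — the ant stops and rotates on the spot through
successive head fixations — is detected as a maximal run of
sub-threshold steps (merging runs separated by less than `gap_merge`)
that additionally satisfies: thorax excursion from the run centroid at
most `r_max`, cumulative |Δorientation| at least `θ_min`, and duration
at least `min_dur`. Defaults: `r_max = 5` mm, `θ_min = 45°`,
`min_dur = 0.4` s, `gap_merge = 0.2` s, with `v_stop` shared with the
speed module. No published numeric criteria exist for this species'
scanning, so these were fixed once as conservative values for 25 fps
millimetre-scale data — long enough to exclude single-frame jitter,
lax enough that a genuine fixation sweep (tens of degrees over a
second) always qualifies — and every run logs them. The count of
head-sweep direction reversals (`n_fixations`) is reported per bout but
not used in statistics. Raising `θ_min` or `min_dur` can only remove
bouts, which the test suite checks as a monotonicity property.

# Route outcomes

The odour band is a rectangle inside the arena (default: 500 × 50 mm
centred in the 700 × 1000 mm window — the band is narrower than the
arena, so walking around it inside the frame is geometrically
possible). Classification is purely geometric:

- **walked_over** — some contiguous upward passage from below the band
  bottom to above its top stays horizontally inside the band's x-extent
  for at least half of its in-span frames (a passage that jumps the
  span between two frames is judged at the interpolated mid-span x).
  The majority rule is the tie-break for paths that straddle a band
  edge; it is recorded with the output.
- **detour** — the ant gets above the band top, but every upward
  passage runs outside the band's x-extent.
- **u_turn** — the ant approaches within `d_app` below the band
  (default 100 mm, configurable; no published value exists for what
  counts as "responding" to the band), never reaches above its top,
  and ends below the band bottom at or beyond the arena's bottom edge
  or below its own starting height.
- **incomplete** — anything else, e.g. a recording that ends
  mid-ascent. Incomplete trips are excluded from outcome denominators.

The four categories are mutually exclusive and exhaustive by
construction, and reflection of x about the band centre leaves them
unchanged. Frequencies carry exact (Clopper–Pearson) binomial
intervals.

# Inference

Experiment-style comparisons are deliberately plain:

- **Control vs test, per nest**: Welch unequal-variance t-tests with
  Satterthwaite fractional df (the pooled test is available by flag).
  Two-sided throughout; no multiplicity adjustment by default, with an
  optional Holm flag. Control is the first sample, so negative t means
  the metric rose under odour.
- **Repeated exposure** (one control day, three consecutive test
  days, same marked individuals): one-way within-subject ANOVA, F =
  MS(condition) / MS(condition × subject) on (k−1), (k−1)(n−1) df —
  df (3, 45) at n = 16, k = 4. The Greenhouse–Geisser epsilon and the
  corrected p are computed and reported but not applied to the headline
  F.
- **A priori Helmert contrasts** on the four ordered conditions:
  (3,−1,−1,−1), (0,2,−1,−1), (0,0,1,−1), each scaled to unit sum of
  squares — control vs all test days; day 1 vs days 2–3; day 2 vs
  day 3. Each contrast is an exact one-sample t on per-subject contrast
  scores (hence invariant to per-subject constants); a
  normal-approximation z with its p-value is printed alongside for
  readers who prefer that convention. With only subject-level scores
  entering, the t is the defensible primary statistic.

# The synthetic forager

Analyses are validated on generated data with known ground truth. The
thorax path is a correlated random walk: step lengths gamma with mean
`p*` and CV `b*`; turning angles wrapped-normal with mean zero and
σ = √(−2 ln c*), so the population mean cosine is exactly `c*` (c* = 0
switches to uniform turning). The head sits `head_offset` mm from the
thorax along the body axis, which oscillates sinusoidally about the
travel direction (±20° at 1 Hz by default), emulating the walking head
sweep.

Foragers additionally follow a small waypoint plan that realises a
scripted band response — *cross* (straight through), *detour* (lateral
excursion past the band edge, ascend outside it, return) or *u_turn*
(approach, turn, exit the bottom). Each step's heading blends the CRW
proposal with the direction to the current waypoint (weight ≥ 0.35),
and whenever the ant strays further than the leg's corridor half-width
from the straight line to the waypoint its next heading points straight
back at it. That bounded-excursion guidance is what makes the three
geometries unambiguous by construction — the property the
classification tests rely on — at the cost of slightly depressing the
realised turning-angle spread in forager (not free-CRW) paths; free
CRWs with `drift_weight = 0` are therefore what the estimator-recovery
checks use. Leaving the arena terminates the trajectory, mirroring the
recording-area windowing of field video.

Stop episodes and scanning bouts are implanted by freezing the thorax
for the scripted duration; scans additionally sweep the body axis
sinusoidally (±60° at 1 Hz by default, i.e. ~240° of cumulative sweep
per second — at least twice every detector threshold). Implant
boundaries are recorded at exact frame times, so detector recall,
precision and boundary error are measurable to the frame.

`simulate_experiment()` reproduces the two study layouts: independent
ants per condition (acute response, 15 per cell), and a within-subject
layout (16 subjects × control + three test days) with per-subject
random intercepts — a log-normal multiplier on step length (SD 0.08)
and an additive shift on c* (SD 0.015), small relative to the condition
effects, giving the repeated-measures error stratum something real to
estimate.

The default condition profiles encode the qualitative field picture,
fixed once: control ants nearly straight (c* = 0.95), fast
(1.5 mm/step ⇒ 37.5 mm/s), about one scan per trip, always crossing;
acutely odour-exposed ants meandering (c* = 0.75), slower (1.0
mm/step), ~4 scans, mostly detouring (20/70/10% cross/detour/U-turn);
the habituation profiles interpolate back toward control across the
three test days (c* = 0.75, 0.87, 0.93; crossing fraction 10%, 40%,
85%). Per-ant scan counts are Poisson around the profile mean, matching
the broad per-ant spread seen in field counts.

## What the generator does and does not emulate

It reproduces the statistical structure the estimators assume — CRW
step/turn statistics, goal-directed ascent, discrete stop/scan events,
the three response geometries, arena windowing. It does **not**
emulate tracking pixel noise, lens distortion, occlusion dropouts,
bark-surface 3-D geometry, or any sensory mechanism; passing tests
demonstrate the *pipeline's* correctness and power under the stated
conditions, not field-data robustness to digitisation artefacts.
Consequently the suite's effect sizes are cleaner than field data
would give, and the power estimates are upper bounds for equally sized
real effects.

# Numerical and degenerate-input conventions

- Wrap convention (−180°, 180°]; wrapping is tested against a
  complex-phasor oracle to 1e−9.
- Straightness degeneracies return flagged sentinels (see above); the
  straightness cut-off is 1e−9 from |c| = 1.
- Zero-variance two-sample comparisons: equal means return t = 0,
  p = 1 with a `zero_variance` flag; unequal means are refused as
  insufficient data rather than reported as infinitely significant.
- The within-subject F guards its 0/0 case (no condition effect at
  machine precision) to F = 0, p = 1, and Helmert contrast scores that
  are zero to rounding are treated as exactly null.
- Metrics tables are written with 17 significant digits so a
  write/read cycle is lossless to well below 1e−12.

# Problem sizes used in the test suite

Module tests run on paths of 50–1,500 frames. Estimator-recovery
checks use 10,000-step CRWs (sampling error ≲ 1% on S and E^a_max);
detector recovery uses 50 foragers with two implants each; route
recovery uses a 500-ant mixture; calibration uses 2,000 null Welch
replicates; and the two end-to-end power checks use 100 replicate
experiments at the study sizes (15 per cell; 16 × 4). The whole suite
completes in a few minutes on one CPU, and `scripts/acceptance.R`
re-derives the same headline numbers from a single `--seed`.

# Known limitations

- Finite-*n* behaviour of `E^a_max` is not modelled; comparisons should
  be made between trajectories of broadly similar length.
- The scan detector's thresholds are assay conventions, not fitted
  quantities; real-data use should start from a sensitivity sweep
  (`theta_min`, `min_dur`) — the monotonicity properties make that
  sweep predictable.
- Band-edge classification uses a majority rule that is sensible but
  arbitrary at exactly 50%; the tie-break is recorded so reanalysis can
  change it.
- The sub-threshold default `v_stop = 0.01` mm/s will classify real
  tracking jitter as movement; with field data a threshold calibrated
  to the digitisation noise floor is advisable.
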