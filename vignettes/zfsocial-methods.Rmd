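---
title: "Methods: models, parameters and validation strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and validation strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfsocial)
```

This vignette is the package's account of its science: what each statistic
assumes, how the synthetic agents work, which parameters matter, and where
the approach has known limits.

## The social index and its time-shifted null

The social index quantifies attraction of a solitary larva toward a
projected dot that moves with larva-like kinetics. The raw signal is the
per-frame Euclidean distance between the animal centroid and the dot
center, restricted to frames on which a dot is displayed. Its mean over a
stimulus epoch (in 5-min chunks) is the observed distance IADr.

A small observed distance is only evidence of attraction relative to what
chance encounters would produce in the same dish with the same two
trajectories. The null used here destroys the temporal correspondence
while preserving everything else: the animal position sequence is
circularly shifted in time against the stimulus sequence, within the
epoch, by 10 offsets placed evenly in (60 s, epoch length − 60 s); each
shift yields a chance distance IADs, and their mean mIADs is the
chance expectation. The index is

$$ SI = \frac{mIADs - IADr}{mIADs} $$

with SI = 1 when the animal rides the dot (IADr = 0), SI = 0 at chance,
and SI < 0 for avoidance. Properties that follow from the construction,
and that the test suite checks: SI never exceeds 1; any trajectory that is
invariant under the shift set (e.g. a stationary animal) scores exactly 0;
SI is invariant under rigid rotations and translations applied jointly to
animal and stimulus.

Two choices were genuinely open:

* **Shift topology.** Shifts wrap circularly *within each epoch* rather
  than spanning the whole multi-hour session. This preserves the marginal
  distribution of both trajectories exactly, keeps the frame count of
  every shifted series equal to the observed one, and makes epochs
  independent scoring units. The configuration is recorded in the result's
  `si_config` attribute.
* **Offset placement.** Only the constraint "> 60 s" and the count 10 are
  fixed by the assay definition; the 10 offsets are spaced evenly in the
  admissible interval, which avoids clustering near either boundary.

Epochs shorter than 120 s plus one frame cannot support the null and raise
a classed error. If mIADs = 0 (animal and dot glued together and
motionless) the index is undefined and returned as `NA` with a warning.

## The bout-swimming agent

No public trajectory corpus accompanies assays of this kind, so validation
rests on simulated agents whose social drive is known by construction.
The agent is deliberately minimal — a discrete-bout random walker with one
social knob — not a biomechanical model.

* Bout times follow a renewal process at `bout_rate` (default **1.5 Hz**):
  a motor refractory of one glide duration plus an exponential interval,
  matching the non-overlapping propulsive bouts of real larvae.
* Each bout rotates the heading by a wrapped-normal turn (SD `turn_sd`,
  default **0.6 rad**). When a dot is shown, the mean turn is the bearing
  error toward the dot weighted by $k/(10+|k|)$; negative `k` steers
  toward the anti-bearing (flight). The half-saturation at `k = 10` keeps
  the knob graded over the tested range `k = 0…20` instead of saturating.
* The bout displacement is gamma-distributed (mean **4 mm**, shape **4**),
  spread over a ~150 ms glide with linearly decaying per-frame weights.
  The resulting mean speed (~6 mm/s) and kinematics are plausible for
  14–15 dpf larvae, the age at which these social assays are run.
* Walls are specular: both position and travel direction reflect, so
  agents slide along the boundary instead of sticking to it. Escape
  maneuvers are integrated in sub-steps so a flight along the wall keeps
  its full recorded speed.
* With `k = 0` the random-number stream never touches the stimulus, so an
  asocial agent's trajectory is *exactly* the same with and without a dot
  at the same seed — the strongest possible form of the null.

The stimulus dot follows a closed Lissajous figure (2:3 frequency ratio,
14 mm amplitudes) — a self-crossing, dish-filling "knot". Its period
(default **140 s**) gives the dot a mean speed of ~1.5 mm/s, matching the
larva it imitates; in `boutlike` mode it advances along the figure in
discrete Poisson-timed steps with dwell in between.

What the agent does **not** emulate: hydrodynamics, body posture and tail
kinematics, distance-dependent modulation of bout vigor, habituation or
learning within a session, and any interaction between two real fish
beyond turn-bias toward the partner's mirrored position. Passing tests on
these agents therefore validate the *statistics* (that SI, the dyad
metrics and the detector recover planted effects of known sign and size),
not any claim about real fish behavior.

## Split-dyad metrics

Two mirrored 50 × 20 mm tanks share a divider wall; coordinates put the
divider at y = 0 with y increasing toward the opposite wall, and the
recording runs at 10 fps (5 min opaque-divider "presocial", 5 min open
"social"). Relative place preference is the mean of (L − y)/L: 1 at the
divider, 0 at the far wall, 0.5 under uniform occupancy; mirroring a
trajectory across the tank midline maps it to 1 − the original.

Orienting is the acute angle between the heading and the divider line,
scored inside the inclusive 45–90° band, and — one deliberate
restriction — only for headings with a positive component *toward* the
divider (`require_toward = TRUE`). Without it, a larva facing directly
away from its partner would also score 90°. The denominator is all frames
with a defined heading. Headings come from frame-to-frame displacement
(the frame format carries centroids only); displacements below
`body_length/10` carry no orientation information and are dropped. Under
a uniform heading distribution on the toward-divider semicircle the band
covers exactly half the angular mass, a property the tests check.

**Known limitation.** For simulated agents the social phase *raises* place
preference strongly but does not raise displacement-based orienting: an
attracted agent ends up at the divider, where wall-reflected bout
displacements read as facing away or parallel. Real larvae hover at the
divider with their body axis angled toward the partner — a posture signal
that centroid displacement cannot carry. The orienting metric is therefore
validated on crafted geometries (perpendicular, parallel, uniform
semicircle, inclusive bounds), while planted social asymmetry is asserted
through place preference.

The motion metric counts frames whose displacement is at least one-third
of the body length (inclusive), and animals below 10% time in motion
(strict) over the whole experiment are excluded. Both boundaries are
exercised exactly in the tests.

## Open field and the stunted classifier

Thigmotaxis is reported as outer-third occupancy: the fraction of tracked
frames at radius r > (2/3)R, which equals 5/9 ≈ 0.556 under uniform
occupancy of the disc. The index has no universal formula; the definition
is attached to the returned value and a `mean_r` alternative (mean r/R,
2/3 under uniformity) is available. Average speed is total path length
over tracked duration, with gap frames removed from both numerator and
denominator; it is reported in input units per second (pixels/s for
uncalibrated recordings, mm/s when a px/mm calibration is supplied at
read time).

An animal is stunted when its length is strictly below the wild-type mean
minus 1.5 wild-type sample SDs (ddof = 1), with the threshold estimated
from the wt stratum only. Two regimes matter:

* **Clean baseline** (stunting confined to mutants): the threshold sits
  1.5 SD below a homogeneous wt distribution, the flagged wt fraction is
  the normal tail Φ(−1.5) ≈ 6.7%, and the flagged mutant fraction recovers
  the planted rate (~78% in the emulated regime).
* **Contaminated baseline** (a sizeable minority of wt also stunted, as
  observed in real clutches): planted stunted wt inflate the wt SD, the
  threshold slides down toward the stunted mode, and recovery degrades.
  This is a genuine property of the 1.5-SD rule, demonstrated in
  `analysis/04_openfield_growth.R`, and the reason the default generator
  regime and the classifier-validation regime are kept distinct.

## Looming escapes

Schedules present looms once per minute in random size × side order
(final sizes 0–12 mm, linear expansion over 500 ms / 15 frames at 30 fps,
placed 10 mm to the left or right of the animal), each preceded by a 20 s
centering grating ending 10 s before onset. Laterality is taken in the
world frame: centroid-only records carry no body axis to define an
egocentric frame, and a fixed frame keeps the mirror-invariance of the
detector testable.

The simulator plants escapes with probability
`plogis((final_diam − escape_p50) · escape_slope)` (defaults: p50 =
**4 mm**, slope = **0.8 /mm**) and executes them as ~67 ms flights at
`escape_speed` (**300 mm/s**, C-start-like) directed away from the loom,
deflected along the wall when cornered. The detector scores an escape when
peak inter-frame speed within 1.0 s of onset (0.5 s expansion + 0.5 s)
exceeds a threshold, by default 5× the session's median moving-frame
speed — adaptive per animal, robust to the zero-speed dwell frames between
bouts. Under the default kinematics this threshold lands near 120 mm/s,
far above routine bout peaks and far below planted escapes; the tests
require ≥ 95% recovery of planted escapes, ≤ 5% false positives on 0-mm
looms, and per-size escape fractions inside the binomial 99% interval of
the planted logistic. Events with no tracked frames in the window are
marked unscorable and leave the denominators.

## Group statistics

Pairwise genotype contrasts use the Tukey–Kramer HSD on group means
(studentized range with the unequal-n correction, family α = 0.05),
computed via `stats::aov` + `stats::TukeyHSD`. A seeded two-sample
permutation test (mean difference, two-sided, add-one correction,
`n_perm ≥ 999`) provides a distribution-free cross-check, and a paired
sign-flip variant serves within-animal phase comparisons. The mixed-model
repeated-measures ANOVA and multiple regression used alongside HSD in the
original analyses are standard fits outside this package's scope; the
HSD + permutation surface reproduces the qualitative group contrasts on
synthetic cohorts (`analysis/06_group_comparisons.R`).

## Numerical and I/O conventions

* Coordinates are millimeters; the circular-arena origin is the dish
  center, the dyad-tank origin the corner where the divider meets the side
  wall. A px/mm calibration divisor is accepted at read time because all
  published thresholds are metric.
* Frame timestamps are interval starts; per-frame quantities belong to
  `[t, t + 1/fps)`. The dyad assay is fixed at 10 fps; the virtual assay
  frame rate is configurable with a 30 Hz default.
* CSV frame streams carry the header
  `t,x,y,heading,stim_x,stim_y,stim_diam,epoch_id`, spell missing values
  `nan`, and are written with 17 significant digits so that
  write-then-read is bit-exact; metadata travels in a JSON sidecar.
* Tracking gaps up to 3 frames are linearly interpolated; longer runs stay
  missing, are flagged, and leave every metric's denominator.
* Band and threshold comparisons are inclusive exactly where the assay
  definitions are inclusive (45–90° bounds, body-length/3 motion); the
  orienting band adds a 1e-9 degree tolerance against radian→degree
  rounding. Exclusion (< 10%) and stunting (< threshold) are strict.
* Every simulator and permutation test takes an integer seed and restores
  the caller's RNG state (`withr::with_seed`); identical seeds give
  bit-identical output.

## Problem sizes

The validation suite runs 100 virtual-assay sessions per attraction gain
(300 s epochs at 30 Hz), 50 dyads (2 × 5 min at 10 fps), one 360-event
loom session (6 sizes × 60 events), a 10,000-animal length cohort, and
50,000-frame analytic occupancy checks. These sizes put Monte-Carlo
standard errors well below every asserted margin while keeping the whole
suite inside a few minutes on a single core.
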