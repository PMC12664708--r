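---
title: "From maze-walking tracker streams to gait, balance, and cognition: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From maze-walking tracker streams to gait, balance, and cognition: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(vrgait)
```

`vrgait` turns 6-DoF motion-tracker recordings of a person walking through
a grid floor maze into spatiotemporal gait parameters, inverted-pendulum
balance metrics, and covariate-adjusted associations with cognitive test
scores. This vignette documents the models, the tunable parameters, the
synthetic-data generator used to validate the pipeline, and the numerical
choices made where the underlying procedures left room for judgement.

## Data model

A recording session consists of three tracker streams — left ankle, right
ankle, and navel — each a time series of 3-D position (metres, global
right-handed frame with Z up) and unit quaternion orientation
(scalar-first, rotating tracker-local axes into the global frame), sampled
nominally at 90 Hz. The ankle trackers are mounted with the local x-axis
pointing along the foot; the navel tracker with the x-axis pointing up.
Timestamps are seconds from session start on a single shared clock.

Tracking dropouts (battery loss, occlusion) appear as timestamp
discontinuities. Any inter-sample interval longer than `max_gap_factor`
(default 3) nominal periods is recorded as a half-open gap covering the
span the missing samples would have occupied. Rather than discarding whole
sessions that contain a dropout, every *stride* that overlaps a gap in any
stream is excluded from all downstream summaries; this is the
finer-grained analogue of session-level exclusion and keeps the rest of a
session usable. Sessions are stored on disk as one CSV per tracker
(`t,px,py,pz,qw,qx,qy,qz`) plus a JSON sidecar with subject, condition,
visit, maze id, rates and recorded gaps; `write_session()` /
`load_session()` round trip exactly to text precision.

## The maze

Mazes live on a 7 x 8 grid of 0.56 m square blocks (56 blocks), entered at
a grid corner, with a unique navigation path to the exit.
`generate_maze()` carves passages with a randomised depth-first search,
which produces a *spanning tree* of the grid graph: between any two cells
there is exactly one simple path, so path uniqueness holds by
construction and is additionally verified in the tests by exhaustive path
enumeration. The exit is drawn among perimeter cells whose path from the
entry spans at least `max(rows, cols)` cells, so degenerate two-corner
mazes cannot occur. "Similar complexity" across a batch of mazes is
operationalised as equal solution-path cell count (`generate_maze_set()`);
no other complexity metric is imposed.

Completion time needs an explicit definition, which this package fixes as:
the time from the first navel sample inside the entry cell to the first
subsequent navel sample inside the exit cell. This is a design choice of
the package and is stated wherever completion times are reported.

## Gait events from shank orientation

The angle $\alpha$ between the ankle tracker's local x-axis (rotated into
the global frame) and the global Z-axis rises from heel strike to toe-off
and falls back to the next heel strike as the shank pivots over the stance
foot. Heel strikes are local minima of $\alpha(t)$, toe-offs local maxima.
`detect_events()` implements this with four deliberately explicit stages:

1. **Smoothing**: a centred moving average of width `smooth_window_s`
   (default 0.1 s). A minimal, parameterised smoother was preferred over a
   named filter because the detection rule is defined on extrema, not on
   a frequency band.
2. **Extremum acceptance**: all plateau-aware local extrema are scanned
   exhaustively; an extremum is kept if its topographic prominence is at
   least `min_prominence_deg` (default 5 deg) and accepted events are at
   least `min_interval_s` (default 0.3 s) apart. This suppresses
   micro-oscillations from shuffling or standing without hard-coding a
   cadence. Plateau ties take the centre sample; boundary samples are
   never events.
3. **Alternation**: within any run of same-kind events only the most
   prominent survives, so heel strikes and toe-offs strictly alternate
   per side.
4. **Sub-sample refinement**: each surviving event is moved to the
   stationary point of a local least-squares *cubic* fitted to the raw
   waveform in a symmetric window (half-width `refine_window_s`, default
   0.22 s, shrunk to stay clear of neighbouring events). The cubic term
   absorbs the waveform's local skew, so the refined time is unbiased on
   clean data while suppressing most of the timing jitter that sensor
   noise induces in a smoothed argmin. Events inside dropout gaps are
   discarded.

On clean simulated walks every ground-truth event is recovered within one
sample (F1 = 1.0); at 2 degrees of per-sample orientation noise the mean
F1 across seeds stays above 0.95, and it degrades monotonically as noise
grows.

## Strides, step classification, spatiotemporal parameters

A stride is the triple heel strike, ipsilateral toe-off, next ipsilateral
heel strike. From ankle positions at the event samples:

* length — horizontal distance between the two ipsilateral heel-strike
  positions;
* time — heel-strike to heel-strike; velocity = length / time (an exact
  identity by construction);
* stance percentage — 100 x (toe-off − initial heel strike) / time,
  the common stance-phase convention given that per-side heel strikes and
  toe-offs are the only events available;
* width — perpendicular horizontal distance from the contralateral ankle
  position at its intervening heel strike to the line joining the two
  ipsilateral heel-strike positions. The source procedure never defines
  width; this standard construction is documented as the package's own.

Steps are classified by foot direction: the projection of the tracker's
x-axis onto the horizontal plane, evaluated at the heel-strike instants
(a literal reading of "between two consecutive heel strikes";
"consecutive" is taken as ipsilateral because all parameters are
stride-level). A stride is *straight* when the absolute wrapped heading
change stays strictly below a threshold, *turn* otherwise. The
conventional threshold range is 20-30 degrees; the default is the
midpoint, 25 degrees. `calibrate_threshold()` formalises the per-subject
manual selection: it takes strides occurring on straight segments of the
maze path, sets the threshold to the largest observed deviation plus a 5
degree margin, and clamps to [20, 30]; with fewer than 5 calibration
strides it warns and falls back to 25.

Only straight strides enter summaries (turning data is scarce in a single
maze traversal, and turn biomechanics differ); summaries report the mean
and the coefficient of variation — sample SD (n−1 denominator, appropriate
for small per-session counts) divided by the mean — for each of the five
parameters.

## Balance: extrapolated CoM and margin of stability

The body is reduced to an inverted pendulum. With CoM horizontal position
$u$ (the navel tracker), CoM velocity $\dot u$, and
$\omega_0=\sqrt{g/\ell}$ where $g = 9.8\ \mathrm{m/s^2}$ and $\ell$ is the
vertical navel-ankle tracker distance, the extrapolated centre of mass is

$$\mathrm{XCoM} = u + \dot u / \omega_0 .$$

Choices the formula leaves open, fixed as follows:

* $\dot u$ — central finite differences on the native 90 Hz timestamps,
  then a zero-phase 2nd-order Butterworth low-pass at 6 Hz
  (reflection-padded to avoid edge transients). 6 Hz keeps stride-scale
  dynamics while removing sample noise.
* $\ell$ — per-session median of the vertical navel-ankle separation;
  the median is insensitive to swing-phase ankle excursions.
* Base of support — ankle trackers alone cannot bound the feet, so each
  foot is given a nominal footprint (0.25 m x 0.10 m, configurable)
  centred at its ankle tracker and oriented by its foot heading; the BoS
  is the smallest rectangle aligned with the step frame (AP axis from the
  cycle's direction of progression, ML axis perpendicular) containing
  both footprints. Coincident feet degrade gracefully to a single
  footprint.
* Margin of stability — evaluated mediolaterally at every heel strike
  with the double-foot BoS at that instant: the signed distance along the
  ML axis from the XCoM to the nearer ML border, positive when the XCoM
  is inside the ML extent. The sign convention (positive = stable) is the
  package's; a single-foot BoS can be obtained by passing the same
  position for both feet.

Per gait cycle, the direction of progression (DoP) is the unit vector from
the CoM at the initial heel strike to the CoM at the terminal heel strike;
cycles with near-zero displacement are flagged and excluded. The
mediolateral CoM displacement is the maximum absolute perpendicular
deviation of the CoM from the DoP line within the cycle; its mean and CoV,
and the mean ML margin, are summarised over straight-stride cycles only,
consistent with the straight-step restriction of the gait stage.

## The synthetic walker

Because no tracker recordings accompany the study design, validation rests
on a simulator with full ground truth. `simulate_walk()` lays alternating
footfalls along the maze solution path with per-step draws from the gait
profile (stride length, time, width means and SDs; stance fraction; sway
amplitude; sensor noise; dropout rate), then emits three 90 Hz streams.

Key modelling decisions:

* **Shank-angle waveform**: a raised cosine in a monotone cycle-phase
  warp (Hyman-monotone cubic spline through the event knots), so the
  local minima and maxima fall *exactly* at the ground-truth heel strikes
  and toe-offs, with locally symmetric curvature; the exact waveform
  shape is otherwise immaterial because only extrema locations carry
  information. Its amplitude is 25 degrees about a 70 degree baseline.
  Phantom half-cycle knots beyond the first and last events make the
  boundary events proper interior extrema.
* **Corner negotiation**: steps that would land within 0.1 m of a maze
  corner pivot *onto* the corner, with the foot heading rotated to the
  corner bisector plus a 15 degree offset whose sign alternates with the
  corner's grid-row parity; a pivot chains directly into the next pivot
  across one-block legs. This guarantees that every stride spanning a
  corner shows a foot-direction deviation of at least 30 degrees — even
  in staircase and Z-jog corner patterns — and is therefore classifiable
  as a turn from the tracker data alone, while within-segment strides
  carry exactly the drawn stride statistics. Turn steps are slowed by
  `turn_slowdown_factor`.
* **CoM**: progresses along the path through the footfall knots with a
  mediolateral sinusoidal sway of amplitude `com_sway_amp`, phase-locked
  so it is zero at every heel strike and peaks toward the stance foot in
  mid single-stance; per straight cycle the maximum DoP deviation then
  equals the sway amplitude.
* **Noise and dropouts**: i.i.d. Gaussian position noise, Gaussian
  orientation noise applied to the angle waveform and the heading, and
  Poisson-count dropout windows of 0.2-0.6 s.

The default condition profiles encode the qualitative contrasts the
pipeline must reproduce: the wall condition has smaller (0.88 vs 1.00 m),
slower (1.18 vs 1.05 s), relatively more variable strides, narrower
width (0.10 vs 0.12 m), higher stance fraction, and smaller mediolateral
sway (0.030 vs 0.040 m) than the no-wall condition. No quantitative
wall-effect sizes are published in text, so these deltas are qualitative
study conditions fixed once, not tuning knobs.

What the simulator does *not* emulate: path-search behaviour (getting
lost), double-support kinematic detail, soft-tissue artefact, or
correlated sensor error. Passing recovery tests therefore demonstrates
the internal consistency of the pipeline under the stated kinematic
model, not field accuracy on human data.

## Synthetic cohorts and studies

`generate_cohort()` draws covariates (age 67.8 +/- 6.3 years truncated at
the 60-year inclusion bound, height 167.7 +/- 8.6 cm, weight 77.4 +/- 17.7
kg, education 16.9 +/- 3.2 years, 16/65 male) and eleven cognitive scores
from truncated normals respecting each instrument's range (see
`cognitive_tests()`). Subject-level gait outcomes are built around the
no-wall profile; planted gait-cognition effects enter this generating
process linearly in the centred scores — not as post-hoc noise on
summaries — so recovering a planted slope exercises the whole chain. The
stride-velocity latent carries its own Gaussian residual about the
profile-implied mean so that regression-based recovery tests meet the
OLS error assumptions exactly.

`simulate_study()` produces the full two-condition x two-visit design:
the same maze within a condition across visits, different mazes across
conditions, a delayed-visit learning effect (stride length +0.04 m,
stride time −0.04 s by default), subject random intercepts per outcome,
lognormal completion times centred at 28.4/26.1 s (no-wall
immediate/delayed) and 64.3/49.7 s (wall), and — by default — a planted
interaction on the mediolateral margin of stability that decreases from
the immediate to the delayed visit in the no-wall condition only. With
`kinematics = TRUE` every session is additionally rendered as tracker
streams via `simulate_walk()`; the outcome-level path generates from the
same profile-level model and is used for Monte-Carlo work where
simulating thousands of full walks would be wasteful. Validation problem
sizes (10 clean sessions for recovery; 1000 null cohorts of n = 100 for
type-I error; 100 replicate studies of n = 40 for power) were chosen to
give Monte-Carlo standard errors comfortably below the margins being
checked.

## Statistical stage

* **Normality screen**: Shapiro-Wilk at alpha = 0.05 per outcome; a
  non-normal, all-positive outcome is natural-log transformed (the log
  base is a convention; natural log is used). Non-positive non-normal
  outcomes are flagged `untransformable` and left alone — no shift
  constant is invented.
* **Adjusted regressions**: one ordinary least squares model per
  (outcome, cognitive test) pair — the per-test reporting structure
  implies separate models rather than one joint model — adjusting for
  age, sex, education, height and weight, on complete cases, requiring at
  least 15 of them. Significance is read at unadjusted p < 0.05; no
  correction is applied across table cells, matching the reporting
  convention, though the full p-values are returned so any family-wise
  correction can be applied downstream.
* **Mixed models**: `outcome ~ condition * visit + (1 | subject_id)`
  fitted by REML through `lmerTest`, with Satterthwaite denominator
  degrees of freedom for the fixed-effect tests (a configuration, not a
  hard-coded method). Random-intercept variances estimated at the zero
  boundary are kept (variance floored at 0) with a logged note. When the
  interaction is significant at 0.05, exactly four follow-up contrasts
  are computed — visit within each condition and condition within each
  visit — with Bonferroni adjustment `p_adj = min(1, 4p)`.

## A worked miniature

```{r example, message = FALSE}
maze <- generate_maze(seed = 42)
walk <- simulate_walk(maze, default_profile("no_wall", seed = 42))
fit <- analyze_session(walk$session, maze = maze)
tidy(fit)[, c("n_straight", "n_turn", "length_mean", "velocity_mean",
              "com_ml_mean", "mos_ml_mean", "completion_time")]
```

```{r mixed, message = FALSE}
study <- simulate_study(20, seed = 42)
mm <- condition_visit_mixed_model(study$outcomes, "mos_ml_mean")
tidy(mm)
glance(mm)
```

## Known limitations

* Event detection is tuned for continuous walking; long standing bouts
  are rejected by the prominence/refractory gates but brief hesitations
  between steps may still yield events.
* The stance-percentage estimate inherits a small negative bias
  (well under 1 percentage point at 90 Hz) from the discrete sampling of
  the toe-off extremum.
* The BoS depends on nominal foot dimensions; absolute margin-of-
  stability values shift with those settings even though contrasts
  between conditions do not.
* Whether turn-step heel strikes should enter balance summaries is not
  settled; this package excludes them for consistency with the
  straight-step restriction.
* The completion timer endpoints and the stride-width construction are
  package definitions; comparisons against other implementations must
  align these conventions first.
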