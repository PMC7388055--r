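---
title: "The lapskill assessment engine: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The lapskill assessment engine: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lapskill)
```

`lapskill` scores two-instrument minimally-invasive-surgery (MIS) training
tasks from instrument-tip trajectory logs. This vignette is the package's
own account of the science inside it: the scene and kinematic model, the
event-detection layer and its thresholds, the metric set and score, the
synthetic-trajectory generator, and the places where the design was
genuinely open and a choice had to be made.

## Coordinate frame and scenes

All coordinates are millimetres in a right-handed frame with the origin at
the centre of the sensor pad, +y up and +z toward the user — the scale at
which optical hand/instrument trackers operate. The default scene places a
200 × 200 × 200 mm workspace cuboid centred 150 mm above the pad, trocar
pivots at (±60, 40, 60), target spheres of radius 8 mm and hollow-cylinder
containers of radius 15 mm. None of these dimensions is canonical; they are
package defaults sized to a desktop tracker's sensing volume, and every one
can be overridden through a scene JSON file (`write_task_json()` /
`load_task(scene_file = )`).

Six tasks are registered, mirroring the classic abstract drills of early VR
box trainers: (1) grip and placement, (2) transfer between instruments and
placement into a container, (3) bimanual traversal of a conduit, (4)
instrument withdrawal and reinsertion while the other hand stabilises an
oval, (5) diathermy of a series of targets, and (6) combined placement and
diathermy. Task 3 is bimanual — both hands play the dominant role and the
dominant-hand option is unavailable; all other tasks accept a configurable
dominant hand.

### The ideal path is the full flawless route

Efficiency of movement is defined against an *ideal path* per hand. We
define it as the complete route a flawless execution follows — including
the collinear grasp approach through a standoff point, the container entry
from above along the container axis, and the withdrawal legs — not merely
the start-to-goal chord. Two consequences: a noise-free execution has
exactly zero off-path time and (numerically) zero path excess, so the two
efficiency readings vanish together in the flawless limit; and the path
length subtracted from the actual tip travel is the honest cost of the task,
so path excess measures wandering rather than penalising required
manoeuvres. The waypoints that define each route are computed from the
scene geometry in one place (`scene_waypoints()`), and the trajectory
simulator schedules its motion through those same points.

The withdrawal task (4) deliberately includes the leg out through the entry
portal in its ideal route: withdrawing is the task.

## The fulcrum model

A laparoscopic instrument pivots at its entry portal, so the intracorporeal
shaft always lies on the segment from the tip to the trocar pivot
(`pose_at()`). The engine needs no orientation data in the logs: the shaft
is reconstructed from tip and pivot alone. This underlies two detectors:
off-tip contact (the shaft, excluding a distal tip zone, touching a target)
and instrument clash (minimum distance between the two shafts).

## Event detection

Detection reduces every error class to a thresholded distance signal over
time. Contact episodes are maximal intervals where the signal is at or
below the contact tolerance; interval boundaries are interpolated linearly
between samples, and episodes separated by less than a debounce window are
merged. The tunables, all fields of `detection_params()`:

| parameter | default | meaning |
|---|---|---|
| `contact_eps_mm` | 1 mm | tolerance beyond a shape boundary that still counts as contact |
| `debounce_ms` | 100 ms | episodes closer than this merge (0 = raw episodes) |
| `tip_zone_mm` | 5 mm | distal shaft length excluded from off-tip contact |
| `corridor_mm` | 10 mm | ideal-path corridor radius for off-path time |
| `grasp_radius_mm` | 10 mm | jaw closure within this distance of an object grasps it |
| `clash_mm` | 5 mm | shaft-shaft distance at or below which instruments clash |
| `container_wall_mm` | 4 mm | wall thickness attributed to container shells |
| `reinsert_hysteresis_mm` | 10 mm | hysteresis band for removal/reinsertion |
| `release_grace_s` | 2 s | withdrawal grace after a grasp/release |
| `trocar_clearance_mm` | 40 mm | boundary contacts this close to the hand's own pivot are exempt |

The metric definitions fix none of these values; each is a declared package
default. Three deserve comment.

**Boundary exemption near the portal.** The instrument necessarily crosses
the workspace limit where it enters, and task 4 requires withdrawing
through that crossing. Counting it as a boundary error would penalise the
required action, so contacts within `trocar_clearance_mm` of the hand's own
pivot are exempt. Boundary errors are therefore hits on the *far* walls.

**Grasp/release exemption.** "Number of contacts with the target sphere" is
an error class, yet grasping the sphere *is* the task. A tip- or shaft-
contact episode is exempt (flagged `counted = FALSE`) when it brackets a
grasp or release of that object — by any hand, since at the instant of a
hand-over the giving jaw is still in contact — or when it starts within
`release_grace_s` after one: the shaft inevitably sweeps past a freshly
placed object on the way out. Everything else is an undue contact. While an
object is held, its contacts with the holding jaw are suppressed outright
(it sits in the jaws).

**Container walls have thickness.** Contact with a container margin is
distance to the cylindrical shell; an idealised zero-thickness shell makes
single touches flicker into many episodes under tremor, so the shell is
given a nominal 4 mm wall and contact means reaching the wall band.

Grasping, transfer and placement are tracked by a small state machine over
jaw transitions: a closure within `grasp_radius_mm` of a free object grasps
it; a closure next to an object held by the other hand transfers it; an
opening releases it, and a release inside the task's goal shape is a
placement. The object's position follows the holding hand's tip, so all
contact detectors see the object where it actually is.

Removal/reinsertion projects the tip onto the entry direction through the
pivot and applies a ±10 mm hysteresis band around the pivot plane, so
chatter at the boundary cannot generate spurious cycles. Burn episodes are
maximal intervals with the diathermy pedal active; an episode is on-target
iff the tip is within the contact tolerance of a designated target at
episode start. Traversal completion (task 3) divides the ideal line into
100 arc-length bins and requires 95% of bins visited while inside the
corridor, per hand.

## Metrics and the final score

`score_session()` composes detection, efficiency, economy, tally and score:

- time `T = t_last − t_first`;
- per-hand efficiency of movement: path excess
  `max(0, actual − ideal length)` and off-path seconds. Both readings are
  computed and reported, because the two standard phrasings of this metric
  (a length difference and a time outside the path) are not equivalent;
  which one a given front-end displays is a presentation choice;
- economy of diathermy: `Σ max(0, d_i − 2 s)` over on-target episodes; the
  threshold is strict, so a burn of exactly 2 s incurs no excess;
- the error tally: episode counts per class, with off-path time and excess
  burn discretised as ceiling-of-seconds, inapplicable classes forced to
  zero, and oval contacts counted only beyond the permitted number (2 by
  default in task 4);
- the final score `S = 100 − Σ n_i v_i`.

Routing the continuous penalties into the score exclusively through their
own discretised error classes keeps the published formula exact while still
letting efficiency and economy influence the score. The score is not
clamped at zero by default — a floor destroys information about very poor
attempts — but scoring functions accept `clamp = TRUE` for display parity
with front-ends that show 0.

Default weights: off-target diathermy 5 (the one canonical value), excess
burn 4, off-tip contact 3, excess oval contacts 3, boundary / target /
container / clash contacts 2, off-path time 1 per discretised second. These
respect the 1-to-5 importance ordering and are fully user-configurable;
`validate_weights()` enforces the [1, 5] range and full class coverage.

## The synthetic-trajectory generator

`simulate_trajectory()` emulates a two-handed session at a given skill
level. Motion is planned as piecewise minimum-jerk point-to-point reaches
(the standard smooth-reach model for aimed human movement) through the
task's waypoint route, with dwell phases for jaw actions and burns. On top
of the nominal plan, two independent Ornstein–Uhlenbeck processes per axis
add tremor (default correlation time 0.25 s) and slower path deviation
(1.5 s). Noise is attenuated to 25% inside *precision phases* — grasps,
releases, burns, touches — with a 0.3 s linear ramp: skilled and unskilled
movers alike converge when they slow down at a target; transit noise is
what separates them.

Errors are injected explicitly, never only emergent. Counts per class are
drawn from the profile's per-minute rates (scaled by the planned task
duration) and scheduled as dedicated excursions — taps on the target or
container wall, a shaft sweep through a target, a touch on a far wall, a
deliberate crossing of the two shafts, off-target burns, over-held burns —
before or after the task proper, so each injection yields exactly one
detectable episode. The manifest records the schedule and the expected
tally. Two ground-truth subtleties: off-path seconds are *measured* on the
noise-free nominal trajectory, and a final excursion hold is stretched so
the planned total lands on a half-integer of seconds, making the
ceiling-of-seconds count robust to tremor-induced jitter at corridor
crossings; excess-burn ground truth comes from the diathermy booleans,
which noise never perturbs.

With the low-noise expert profile, the detected tally equals the manifest
exactly (the package asserts this across all six tasks and many seeds). With
the novice profile, tremor and path deviation produce additional *emergent*
errors — split contact episodes, corridor excursions, boundary grazes — so
detected counts may exceed the manifest. That asymmetry is intentional: the
manifest is a lower bound that becomes exact when kinematic noise stays
inside the detection clearances.

### Skill profiles

| field | novice | intermediate | expert |
|---|---|---|---|
| speed (mm/s) | 35 | 55 | 80 |
| tremor SD (mm) | 3.0 | 1.8 | 0.8 |
| path deviation SD (mm) | 4.5 | 3.0 | 1.5 |
| overshoot probability | 0.30 | 0.15 | 0.05 |
| boundary hits (/min) | 6 | 2 | 0.3 |
| clashes (/min) | 10 | 3.5 | 0.15 |
| off-target burn prob. (per target) | 0.5 | 0.2 | 0.05 |
| burn overhold SD (s) | 1.2 | 0.5 | 0.1 |

The presets are ordered (expert ≤ intermediate ≤ novice in tremor and
deviation) and were chosen once as a realistic picture of the construct:
complete novices working against the fulcrum's motion inversion collide
often — about one instrument clash per six seconds of bimanual work and one
boundary hit per ten — while experts almost never do. The clash and
boundary rates matter most in the traversal task, whose only applicable
error classes they are; at these defaults the expert-novice median score
gap exceeds 10 points on every task (verified at 50 seeds per cell in the
test suite). Tremor magnitudes bracket the ~1 mm accuracy reported for
desktop optical trackers.

What the generator deliberately does **not** model: biomechanical hand/arm
dynamics, haptic interaction forces, sensor noise and dropout of a real
tracker, learning within a session, or error *recovery* behaviour (a real
novice who drifts off the conduit re-traces; the simulated one just
continues). Passing tests on synthetic data therefore demonstrate that the
detection and scoring layers are correct and discriminating on motion with
realistic kinematic statistics — not that the score is valid for real
trainees, which only a study with human subjects can show.

## Numerical choices and degenerate inputs

- Episode boundaries are interpolated linearly in the distance signal, so
  event times have sub-sample precision; diathermy episodes are bounded at
  sample times because the pedal is a sampled boolean.
- All time integrals use actual timestamps; the engine never assumes the
  nominal sampling rate (60 Hz default in the simulator) is exact or
  uniform.
- Trajectory logs are validated on ingestion: missing columns, non-finite
  values and non-monotone timestamps are rejected with the offending row
  number. A file with one hand absent is accepted, that hand parked at its
  pivot with the jaw open — a parked hand sits in the portal-clearance zone
  and triggers nothing.
- A tip coinciding with its pivot has no defined shaft; `pose_at()` refuses
  it. Zero-length polyline edges and degenerate shapes are rejected at
  construction.
- CSV output is byte-deterministic (`%.12g`, LF endings), so identical
  seeds give bitwise-identical files; round-trips agree to well below
  1e-9 mm.
- The simulator uses one seeded Mersenne-Twister stream and restores the
  caller's RNG state on exit.

## Problem sizes used in the checks

The packaged tests run the geometry oracles on hundreds of randomised
instances (dense-sampling oracles at 250–4000 points per segment), the
event layer against per-sample classifiers on 100 random trajectories,
manifest recovery on all 6 tasks × 10 seeds, and skill separation at 50
seeds per task and profile — sizes at which the stochastic margins above
are comfortably resolved while the whole suite stays fast.

## Known limitations

- Contact detection treats the instrument as a line segment and objects as
  analytic solids; there are no meshes, no physics, and no object dynamics
  beyond "held objects follow the jaw".
- The grasp-exemption and release-grace rules encode a judgement about
  which contacts are "the task itself"; alternative conventions (e.g.
  counting every touch) are expressible only by post-processing the event
  log, which retains all episodes with their `counted` flags.
- Oval contacts are pooled across hands against a single permitted count.
- The session store is a flat JSON file per subject — adequate for a
  training workstation, not a multi-user database.
- Difficulty levels per exercise are out of scope; the scene JSON override
  is the extension point.
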