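# lapskill

A headless assessment engine for basic psychomotor skill tasks in minimally
invasive surgery (MIS). Gesture-tracked box/VR trainers record the 3D motion
of two instrument tips while a trainee performs short abstract tasks —
gripping and placing a sphere, transferring it between instruments, running
a conduit bimanually, withdrawing and reinserting an instrument, cauterising
targets. `lapskill` implements everything such a trainer needs *behind* the
screen: the six task scene definitions, trajectory-log I/O, contact and
event detection under the fulcrum (trocar-pivot) constraint, the standard
five-parameter metric set, and a weighted-error final score. A seeded
synthetic-trajectory simulator with skill profiles and an error-injection
manifest stands in for the tracking hardware, so the whole pipeline is
testable without a device.

The package is aimed at surgical-simulation researchers and engineers who
need a reproducible, scriptable scoring back end — for developing metrics,
benchmarking detection thresholds, or generating labelled motion data.

## The metric set and score

Each attempt is summarised by five parameters:

- **Time** `T` — seconds from the first to the last sample of the attempt;
- **Efficiency of movement** per hand — the excess of the actual tip-path
  length over the ideal path length (mm), and the time the tip spent outside
  a corridor around the ideal path (s);
- **Economy of diathermy** — excess burn time `D = Σ max(0, d_i − 2 s)` over
  on-target burn episodes `d_i` (only time *strictly* beyond 2 s counts);
- **Errors** — episode counts `n_i` over nine error classes (off-tip contact,
  workspace-boundary contact, undue target contacts, container-margin
  contacts, instrument clash, excess oval contacts, off-path time, off-target
  diathermy, excess burn time), each applicable to a published subset of the
  six tasks;
- **Final score** `S = 100 − Σ n_i · v_i`, with integer weights
  `v_i ∈ [1, 5]` (off-target diathermy fixed at the maximum, 5). An
  error-free attempt scores exactly 100; the score is not clamped by
  default, so very poor attempts can go negative.

The continuous penalties enter the score through their own error classes
after ceiling-of-seconds discretisation, which keeps the formula exact.

## Worked example

Simulate an intermediate-skill attempt at the diathermy task and score it:

```r
library(lapskill)
task   <- load_task(5)                                    # Diathermy
sim    <- simulate_trajectory(task, "intermediate", seed = 42)
result <- score_session(sim$trajectory, task)
print(result)
#> Task 5 attempt: score 84.0 (completed), 25.28 s
#>   right hand: path excess 708.8 mm, off-path 5.52 s
#>   excess burn time: 0.38 s
#>   errors:
#>     WORKSPACE_BOUNDARY: 1 (weight 2)
#>     DIATHERMY_OFF_TARGET: 2 (weight 5)
#>     EXCESS_BURN_TIME: 1 (weight 4)
```

The attempt completed (all five targets cauterised) in 25.3 s. The simulated
operator wandered: 709 mm of tip travel beyond the ideal route and 5.5 s
outside the corridor (reported, but not an error class for this task), hit
the workspace limit once (2 points), burned off-target twice (2 × 5 points)
and held one burn past the 2-second threshold (ceil(0.38 s) → 1 count,
4 points), for a score of 100 − 16 = 84. Every one of those errors was
injected deliberately and recorded in the ground-truth manifest:

```r
print(sim$manifest)
#> Injection manifest: task 5, profile intermediate, seed 42
#>   WORKSPACE_BOUNDARY: 1
#>   DIATHERMY_OFF_TARGET: 2
#>   EXCESS_BURN_TIME: 1
```

Scoring real logs works the same way: `read_trajectory("session.csv")`
(CSV or JSON-Lines, one row per sample: time, per-hand tip position in mm,
jaw state, diathermy state), then `score_session()`. Attempts can be
appended to a per-subject session store (`save_attempt()`) and summarised as
immediate or terminal feedback (`feedback_report()`).

A command-line launcher with `score | simulate | report | validate`
subcommands is installed under `inst/cli/lapskill`:

```sh
Rscript inst/cli/lapskill simulate --task 1 --profile novice --seed 7 --out run1
Rscript inst/cli/lapskill score --trajectory run1/trajectory.csv --task 1 --out run1
```

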