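# gazedecode

Simulation and analysis of oculomotor learning in a gaze-controlled
human-machine interface with systematically distorted saccade-endpoint
decoding.

## The problem

Assistive devices can let users select objects by looking at them: the
device decodes the intended target from the landing point of the primary
saccade. Decoding errors then come both from oculomotor variability and
from the system itself. A productive way to study how users cope is to
*impose* a known systematic error and watch them adapt. `gazedecode`
implements such a simulated interface and its complete analysis pipeline:

* Eight objects on an invisible circle (radius 7 deg of visual angle)
  around fixation; each object owns a wedge-shaped target area out to
  9 deg, spanning ±22.5 arc deg. A constant **clockwise 45 arc-deg
  rotation** is added to every detected saccade endpoint before decoding,
  so aiming at an object always selects its clockwise neighbour. Feedback
  is either *motor* (a dot at the distorted endpoint) or *action* (the
  decoded object highlighted).
* The only way to be decoded correctly is to aim at the **optimal point**,
  45 arc deg *counterclockwise* of the intended object — a visuomotor
  rotation learning problem. Writing θ for the clock angle of a saccade
  endpoint and θᵢ for the intended object's position, the pipeline tracks
  the signed angles (clockwise-positive)
  `angle_to_intended = wrap(θ − θᵢ)` and
  `angle_to_optimal = wrap(θ − (θᵢ − 45°))`; learning drives the first
  from 0 toward −45° and the second from +45° toward 0.

The package is for researchers in oculomotor control, sensorimotor
learning and gaze-based interaction who want a fully testable, data-free
replica of this paradigm: every stage — online saccade detection (velocity
> 100 deg/s and 3 deg travel for onset; 3-sample mean < 30 deg/s for
offset), validity filtering, endpoint angles, area-based trajectory
curvature (rotation to a rightward saccade, 24-step resampling, signed
trapezoidal area), permutation statistics and Hartigan's dip statistic —
can be exercised against a synthetic-data generator with known ground
truth (minimum-jerk kinematics, error-based and reward-based learners,
two-session structure with savings).

Notable internals: the dip statistic is computed *exactly* (bisection over
the band half-width with convex-minorant/concave-majorant feasibility, in
C++), with Monte-Carlo p-values against the uniform null; the mixed ANOVA
reports classical split-plot F values with permutation p-values
(between-label and within-participant permutation schemes); the
learning-trend test reduces each participant's per-trial decoding outcomes
to a logistic slope and sign-flip-tests the slopes.

## Worked example

Simulate a small two-session cohort (8 participants, 10/80/10 trial
layout, counterbalanced motor/action feedback order, savings 0.8) and run
the full analysis:

```r
library(gazedecode)
cfg <- pipeline_config(seed = 42, n_participants = 8,
                       layout_args = list(n_pre = 10, n_feedback = 80,
                                          n_post = 10, early_n = 10,
                                          late_n = 10),
                       n_perm = 999, n_mc = 199)
cohort <- run_simulate(cfg, out_dir = tempdir())
print(cohort)
report <- run_analyze(cohort, cfg)
print(report)
```

```
Simulated cohort: 8 participants, 1600 trials (endpoint fidelity)
  valid decoding rate by session: S1 0.466, S2 0.981
Analysis report
  exclusions:
                      reason n
 no primary saccade detected 0
     invalid primary saccade 0
  angle to optimal point by condition cell (arc deg):
        order feedback phase  mean    sd
 action-first   action early 46.50  7.52
 action-first   action  late  4.27 10.25
 action-first    motor early 11.51  8.48
 action-first    motor  late -0.60  8.07
  motor-first   action early  8.98  7.69
  motor-first   action  late -0.20  7.99
  motor-first    motor early 45.95  7.00
  motor-first    motor  late  1.37  6.05

[learning_trend]
Permutation t-test (per-participant logistic slopes, sign-flip)
  t = 5.067, p = 0.007 (greater, 999 permutations)

[baseline_pre_s2]
Permutation t-test (sign-flip)
  t = 0.897, p = 0.48 (two.sided, 999 permutations)

[early_vs_late]
Permutation t-test (sign-flip)
  t = 29.81, p = 0.001 (greater, 999 permutations)

[dip_session1]
Hartigan's dip test for unimodality (Monte-Carlo uniform null)
  D = 0.05458, n = 500, p = 0.005 (199 null samples)

[dip_session2]
Hartigan's dip test for unimodality (Monte-Carlo uniform null)
  D = 0.01744, n = 500, p = 0.29 (199 null samples)
```

Reading the output: in each participant's *first* session the early-phase
angle to the optimal point sits near +45 arc deg (saccades still aimed at
the intended object) and collapses toward 0 by the late phase — adaptation
to the rotation. In the *second* session (the other feedback type) the
early angle already starts low (≈ 9–12 arc deg): savings transferred
across feedback types, which also drives the order × feedback interaction
in the mixed ANOVA and the session difference in decoding rates (0.47 vs
0.98). The pooled session-1 angle distribution is bimodal (participants
are either pre- or post-discovery; dip p = .005) while session 2 is not
(p = .29), and the session-2 pre-learning baseline does not differ from
zero (p = .48) — extinction of the learned aim between sessions.

`run_report(report, "out/")` writes the markdown summary, CSV tables and
figures (learning curve, angle-by-phase, curvature-by-phase);
`inst/cli/gazedecode.R` wraps simulate/analyze/report for shell use.

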