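---
title: "Methods: simulating and analysing gaze-based target decoding under a distorted interface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing gaze-based target decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and the model of the interface

`gazedecode` studies oculomotor learning in a simulated gaze-controlled
human-machine interface. Eight objects sit on an invisible circle of radius
7 deg of visual angle around a central fixation cross; each object owns a
wedge-shaped *target area* reaching from the cross out to 9 deg and 22.5 arc
deg to either side of the object, so the eight areas tile the disk exactly.
A user selects an object and indicates it with a single saccade. The
interface detects the saccade endpoint online, adds a constant **clockwise
45 arc-deg rotation** (the distortion, constant for the lifetime of a scene
object), and decodes whichever object's target area contains the distorted
endpoint; if the endpoint lies beyond 9 deg, no object is decoded and a
"too far" message is shown. Feedback is either *motor* (a 1-deg red dot at
the distorted endpoint) or *action* (the decoded object coloured red).

Because of the rotation, aiming at the intended object always lands the
distorted endpoint in the clockwise neighbour's area. The unique aim that
both decodes the intended object and centres the motor feedback on it is
the **optimal point**, 45 arc deg counterclockwise of the intended object.
Learning to use the interface is therefore a visuomotor rotation problem:
the aim direction has to rotate by -45 arc deg.

### Coordinate and sign conventions

Screen positions are Cartesian degrees of visual angle, origin at the
fixation cross, y up. Angular positions are *clock angles*: arc degrees
clockwise from 12 o'clock (`clock_angle()`, `clock_to_xy()`). Two signed
conventions coexist deliberately, mirroring how such experiments are
reported:

* **Endpoint angles** (`signed_angle()`) are clockwise-positive. The angle
  to the optimal point always leads the angle to the intended object by
  +45 (mod 360): an unadapted saccade has angle-to-optimal +45 and
  angle-to-intended 0; a fully adapted one has 0 and -45.
* **Curvature** is counterclockwise-positive: deviation of the trajectory
  away from the straight start-to-end line in the counterclockwise
  direction yields a positive index.

### Boundary decisions

The decoding rule uses the half-open angular interval `[-22.5, +22.5)`
clockwise around each object. The half-open choice guarantees that the
target areas *partition* the disk (every endpoint within 9 deg decodes to
exactly one object); the task description does not dictate a tie-break, so
the package fixes one and tests the partition property on random grids.
A point exactly on the 9-deg circle counts as inside; the origin decodes by
the same angular rule with its clock angle defined as 0. These choices only
matter on measure-zero sets but keep every sweep and simulation
deterministic.

## Saccade event detection

Streams are uniformly sampled at 1000 Hz. Speed is a two-point backward
difference (`estimate_velocity()`), causal to match the online setting; a
centred moving-average smoother is available but off by default because the
synthetic streams are noise-free.

Two detector roles exist:

* **Online trigger** (`detect_onset_online()`, `detect_offset_online()`):
  the simulated system's criteria — onset when speed exceeds 100 deg/s *and*
  the eye has travelled at least 3 deg from the fixation cross (measured
  from the cross, since the criterion's purpose is to ignore fixational
  jitter near it); offset when the mean speed over the last three samples
  drops below 30 deg/s, the endpoint being the last of those samples. The
  travel criterion intentionally delays the trigger well past kinematic
  onset; it times the display change, not the analysis.
* **Offline parser** (`parse_trial()`): finds saccades at the 100 deg/s
  crossing and then *backdates* onset to the start of the velocity rise
  (the sample after speed last dropped below a 10 deg/s baseline). Without
  backdating, the crossing lags true onset by up to ~9 ms for 3.5-deg
  minimum-jerk saccades; with it, onset error on synthetic streams is
  1-2 ms. The offset rule is shared with the online role. The same parser
  serves both roles throughout, so online and offline endpoints agree by
  construction on clean streams.

Validity filters: a primary saccade needs amplitude in \[3.5, 10.5\] deg,
duration < 100 ms, latency > 100 ms; a secondary saccade needs amplitude
< 5 deg, duration < 100 ms and latency (from primary offset) in
\[100, 500\] ms. Bounds are inclusive exactly where stated; the latency
window for secondaries is closed on both ends, a choice the package makes
explicitly since inclusivity at the boundary is not dictated by the rules
themselves.

## Per-trial metrics

The **curvature index** rotates each trajectory so it becomes a rightward
saccade, resamples the perpendicular deviation to 24 equally spaced time
steps by linear interpolation, and integrates it over normalised time in
\[0, 1\] with the trapezoidal rule (the quadrature is the package's choice;
24 steps is the method's fixed resampling length). The result is a *signed
net* area — the sign carries the direction information the analysis needs
(away from versus toward a competing object), which is why the absolute
area variant is not used. The index is invariant to rotation, translation
and uniform time rescaling of the trajectory, and flips sign under
mirroring; both invariances are property-tested.

**Phases** partition a session: `pre` (first 20 circle-off trials),
`early` (first 20 feedback trials), `mid`, `late` (last 20 feedback
trials), `post` (final 20 circle-off trials). Window sizes are
configurable (`session_layout()`); 20-trial early/late windows are the
defaults the analyses use.

`decoding_outcome_table()` exports the per-trial binary valid-decoding
series with condition covariates and the trial number centred within the
feedback phase — the exact input a binomial mixed model (e.g. with AR(1)
trial correlation) would take. Fitting such a model is intentionally out of
scope here; the package instead ships a bespoke trend test (below).

## Statistics

**Permutation t-tests** (`perm_ttest()`): sign-flip permutation for paired
and one-sample tests, group-label permutation for two independent samples;
the t statistic is the test statistic and p-values use the add-one formula
`(b + 1) / (n_perm + 1)`, so they are never zero and are reproducible given
a seed. Identical pairs give p = 1 (every flip reproduces the data);
constant non-zero differences are reported as degenerate rather than
silently tested.

**Permutation mixed ANOVA** (`perm_mixed_anova()`): classical split-plot F
values from `aov()` with an `Error(participant/(within))` stratification on
a balanced table of cell means (balance is enforced with an explicit error,
since dropping participants to restore balance is an analysis decision the
user should make consciously). Permutation schemes: between-participant
labels are permuted across participants for the between main effect;
within-condition cell labels are permuted within each participant for
within effects and all interactions. The parametric F and df are reported
alongside the permutation p, which is how such analyses are normally
written up. The permutation scheme is logged per effect in the output
because published implementations differ in exactly this respect.

**Hartigan's dip** (`dip_statistic()`): the statistic is computed *exactly*
(not from tables) as the minimal sup-norm distance between the empirical
CDF and the class of unimodal CDFs. The implementation (C++) runs a
bisection on the band half-width d and decides feasibility of a unimodal
CDF inside the band via greatest-convex-minorant / least-concave-majorant
constructions, including the case of an atom at the mode and the exact
compatibility of the two sides across the modal interval (the attainable
end-value intervals are computed, not assumed compatible — the
compatibility constraint does bind on a few percent of random samples).
During development the implementation was validated to 1e-11 against an
independent linear-programming minimisation over piecewise-linear unimodal
CDFs; a frozen set of those exact values guards the implementation in the
test suite. `dip_test()` draws its null from uniform(0, 1) samples of the
same size (the classical reference distribution) by Monte Carlo. The exact
computation scales roughly quadratically near the feasibility boundary, so
the pipeline caps dip input at `dip_max_n = 500` values (seeded
subsample) — against modes separated by tens of arc degrees the test's
power at n = 500 is effectively 1, so the cap costs nothing but keeps
repeated analyses fast.

**Holm correction** (`holm_correct()`): base R's step-down `p.adjust`
plus explicit decisions at the familywise alpha.

**Learning-trend test** (`learning_trend_test()`): the stand-in for a full
binomial GLMM. Each participant's outcome series is reduced to a logistic
slope on centred trial number (IRLS via `glm`); participants with constant
or separable outcomes fall back to a ridge-penalised IRLS fit (penalty on
the slope only) and are flagged — separation is expected for learners that
converge to near-perfect decoding, and the penalised slope keeps them in
the analysis with a bounded, correctly signed estimate. The participant
slopes then enter a one-sample sign-flip permutation test of mean slope
> 0. Type-I calibration of the whole two-stage procedure is verified by
simulation in the test suite.

## The synthetic-data generator

The generator produces the statistical structure the analysis pipeline
assumes, not a biophysical eye model:

* **Kinematics**: minimum-jerk position profiles; duration from the main
  sequence `duration = 2.2 x amplitude + 21` ms. These are standard
  textbook values for human saccades, chosen once as sensible stand-ins —
  real recordings are emulated, not reproduced — and both are
  configuration-exposed. Endpoint noise is isotropic Gaussian
  (SD 0.5 deg, roughly 5-10% of a 7-deg amplitude); aim-direction noise is
  Gaussian on the clock angle (SD 5 arc deg, typical directional scatter);
  primary saccades undershoot with gain 0.9; a 0.15-deg sinusoidal bow
  gives trajectories realistic curvature (index about 2 x 0.15 / pi).
  Latency is lognormal with median 350 ms (sdlog 0.15) plus a 60-ms
  increment during early learning, so the latency-by-phase pattern can be
  exercised qualitatively.
* **Session structure**: 20 circle-off baseline trials, 200 feedback
  trials, 20 circle-off trials; intended objects drawn uniformly (a
  per-participant preference vector would be a straightforward extension;
  uniform matches the instruction to use all objects). Fixation is held
  500-1000 ms (uniform) before the go signal. Feedback appears 19 ms after
  the detected saccade offset, emulating the measured display delay.
  A corrective secondary saccade toward the learner's *current goal*
  follows the primary after 150-350 ms — once the aim has shifted to the
  optimal point, post-secondary eye positions approach it, reproducing the
  qualitative secondary-saccade pattern.
* **Learners**: `error_based` shifts the aim by eta times the signed
  angular error of the feedback (the classic adaptation rule; under action
  feedback the error signal is quantised to the decoded object's
  position); `reward_based` is win-stay/lose-shift with a Gaussian
  exploration kernel that shrinks on success. The defaults are eta = 0.15
  and a per-participant *engagement delay* drawn uniformly from 10-80
  feedback trials, during which feedback is ignored. The delay models the
  time participants need to discover the contingency; it staggers
  convergence across a cohort, which is what makes the pooled session-1
  angle distribution bimodal (mass near +45 before discovery, near 0
  after). Both learner modes are illustrative instruments for exercising
  the pipeline, not claims about human learning mechanisms.
* **Savings**: session 2 starts with a neutral aim (baseline circle-off
  behaviour is unaffected by prior learning, by construction); at the
  first feedback trial the stored aim offset is retrieved scaled by the
  savings coefficient, the learning rate is boosted (x2 at full savings),
  and the engagement delay shrinks by the same factor. `savings = 1` makes
  session-2 early performance far better than session-1 early;
  `savings = 0` reproduces session-1-like learning. The package default is
  0.8 — clear but imperfect transfer.

Two fidelity levels: `"stream"` synthesises full 1 kHz gaze streams and
pushes every trial through the online detector and offline parser (so
latencies, amplitudes, curvature and validity flags come from detection,
as for real data); `"endpoint"` uses the generator's landing points
directly and is two orders of magnitude faster — large cohort simulations
(hundreds of cohorts for calibration checks) use it, and it leaves
curvature unset rather than fabricating it.

**What the generator does not emulate**: fixational eye movements, blinks
and artifacts, pupil data, head movement, screen pixel space, and any
trial-aborting behaviour. Detection on synthetic streams is therefore
nearly noise-free; passing detection-fidelity tests shows the detector
implements its criteria correctly, not that it would be this accurate on
noisy recordings. Likewise, the learning patterns the test suite verifies
show that the pipeline *recovers structure the generator put in* — they
validate the analysis chain, not any claim about human behaviour.

## Numerical choices and problem sizes

Angle wrapping uses `(-180, 180]` for signed angles and `[-180, 180)`
for the decoding membership rule (matching its half-open interval). The
dip bisection runs to an interval of 1e-13 with 1e-11 feasibility
tolerances, comfortably inside the 1e-6 agreement checked against the LP
oracle. `nls` fits in `estimate_learning_rate()` fall back to a log-linear
regression when they fail to converge.

The test suite and acceptance checks use fixed seeds throughout and the
following problem sizes, chosen to make the checks statistically decisive
while keeping a full run comfortable on one CPU: 10^5 random points for
decoder-oracle equivalence; 2000 null simulations for type-I calibration
of the permutation tests (199 permutations each); 200 simulated cohorts of
22 participants for the savings comparison; 20 cohorts for the bimodality
check against a 499-sample dip null at n = 500; 1000 random saccades for
detection fidelity.

## Known limitations

* The exact dip computation is O(n^2)-ish near its feasibility boundary;
  for samples beyond a few thousand points, subsample (as the pipeline
  does) or expect seconds per statistic.
* The permutation mixed ANOVA refits `aov()` per permutation; with the
  default 10000 permutations a 2 x 2 x 2 design on 22 participants takes
  a few minutes. Analyses that only need a quick look should lower
  `n_perm`.
* The reward-based learner's convergence time depends strongly on its
  exploration kernel; it is provided for qualitative contrasts with the
  error-based learner, and the parameter-recovery tooling targets the
  error-based rule only.
* `estimate_learning_rate()` assumes immediate engagement (no delay) and
  motor feedback; with the default staggered delays it underestimates eta.
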