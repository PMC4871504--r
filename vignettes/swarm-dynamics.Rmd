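---
title: "Modelling flying-insect swarms: dynamics, noise, and statistical evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling flying-insect swarms: dynamics, noise, and statistical evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`swarmsim` simulates swarms of flying insects (midges, fruit flies, locusts,
moths — and, as a non-insect curiosity, bats) as interacting self-propelled
agents, and provides the statistical machinery to ask how closely a simulated
swarm resembles a reference trajectory dataset. This vignette is the
package's own account of the model, its parameters and defaults, the
numerical choices made, and what the included tests do and do not establish.

## The dynamics model

Each insect `i` is a unit-mass point agent with position `r_i`, actual
velocity `v_i`, and a *preferred* velocity that the force model requests
before collision avoidance has its say. The preferred acceleration is the
sum of three force groups:

* **Interaction forces** from neighbours within three concentric zones:
  repulsion inside `r_rep`, velocity alignment between `r_rep` and `r_ali`,
  attraction between `r_ali` and `r_att` (with `r_att >= r_ali >= r_rep >= 0`).
  For each zone the neighbour influences are averaged and weighted by
  `chi_rep`, `chi_ali`, `chi_att`. A piecewise indicator `g(x)` (-1 / 0 / +1
  across the three zones) selects whether a neighbour contributes its unit
  relative position (pushing away or pulling closer) or its unit relative
  velocity (alignment). Zone boundaries are half-open exactly as the zone
  definition states: `[0, r_rep)`, `[r_rep, r_ali)`, `[r_ali, r_att]`.
* **Self-propulsion forces**: quadratic air drag `-gamma |v| v`, and a
  stimulus response that is zero unless the stimulus lies within the visual
  range `r_res`. A pursuit target attracts with constant magnitude
  `chi_res`; a predator repels along the away-direction rotated about the
  world y-axis by a uniform random angle in `[-pi/2, 0]`, which places the
  escape heading anywhere in the 90–180 degree sector away from the threat —
  fleeing with deliberate unpredictability.
* **An inherent-noise force**, described below.

Time stepping is explicit Euler, exactly in the order the position-update
algorithm prescribes: neighbours are classified by `r_att`; forces are
accumulated; `v_pref = v + F dt`; the collision-avoidance operator maps all
preferred velocities to actual velocities; positions advance by `v dt`.
No higher-order integrator is used — the model is stated as a discrete
update rule, and the evaluation metrics are computed by the same finite
differences, so a fancier integrator would change the model rather than
merely its accuracy.

### Friction: quadratic versus linear

The drag law is written as a product of the scalar speed and the velocity
vector, which we read as quadratic drag `-gamma |v| v`. Because the
typography admits a linear reading (`-gamma v`), a `drag_form = "linear"`
switch is provided; all shipped scenarios use the quadratic form. Either
way dissipated power `F . v` is non-positive, which the property tests
check over random states.

### The noise force

Real insect trajectories are irregular at a fine scale even in still air;
this "inherent noise" is modelled as an explicit stochastic force, and the
package implements the four classical candidates:

* `white` — independent uniforms on `[-1, 1]` per component, scaled by `gain`;
* `gaussian` — `lambda * sqrt(-2 log W1) * sin(2 pi W2)` per component from
  two uniforms. This is precisely the Box–Muller transform, so each
  component is exactly `N(0, lambda^2)`: we document the variance as
  `lambda^2` (not `lambda^2/2` — the `sin` branch does not halve the
  variance, as a Monte-Carlo check in the test suite confirms).
  `W1` is drawn strictly in `(0, 1]` so the logarithm is finite;
* `perlin` — a smooth vector field: three scalar gradient-noise channels
  evaluated at `r/scale` and multiplied by `gain`. The three channels are
  one seeded noise instance sampled at three large fixed coordinate offsets
  (constants in the source); this keeps one lattice per seed while making
  the channels effectively independent;
* `curl` — the curl of the Perlin vector potential. Being a curl, the field
  is divergence-free: insects are swirled, never compressed into sources or
  sinks, and simulated trajectories stay smooth at the step scale. This is
  the default, and the noise the shipped scenarios use.

`scale` and `gain` are two of the eleven model parameters, so the noise
spec's own copies always track the dynamics parameters at run time; the
spec object contributes the noise kind, the Gaussian `lambda`, and the
lattice seed. Smaller `scale` means the field varies on shorter length
scales (noisier trajectories); larger `gain` means stronger noise forces.
A property test confirms the smoothness ordering (mean spatial gradient
decreases as `scale` grows).

Curl derivatives use central finite differences with step `h = 1e-4 *
scale` by default. A subtlety worth recording: if the *divergence* of the
curl field is probed with the same symmetric stencil and the same `h`, the
mixed second differences cancel identically and the measured divergence is
roundoff (~1e-13) for any `h`. The refinement test therefore probes with an
independent, much finer divergence stencil, which exposes the expected
second-order decay of the residual divergence in the curl step.

### Collision avoidance

Preferred velocities are mapped to collision-free actual velocities by a
reciprocal velocity-obstacle operator in 3D: each neighbour induces a
half-space constraint derived from the truncated velocity-obstacle cone
(each agent of a pair takes half the needed correction), and each agent
receives the feasible velocity minimising the 2-norm distance to its
preference, capped at `max_speed`, via an incremental linear program. The
LP lives in `src/` (C++) because it runs once per agent per step — the same
reason the reference implementations of this algorithm family are C++.

Two degenerate geometries need deterministic tie-breaks: a relative
velocity lying exactly on the cone axis is pushed perpendicular to the
*cone surface* (not the axis — a purely lateral push would leave the
relative velocity inside the obstacle), and already-overlapping pairs are
pushed apart within one time step. When no feasible velocity exists (very
dense neighbourhoods), the insect is stopped for that frame
(`infeasible_policy = "zero_velocity"`) or the computation retries with a
halved step (`"halve_step"`); stopping is the default. The
no-interpenetration contract (min pairwise distance at least `2 *
agent_radius` minus 1% discretisation slack) is verified over 500 steps of
100 densely packed swirling agents; the contract holds in the feasible
regime, while under deliberately infeasible crowding (e.g. all agents
forced onto one point) stopped agents can be approached closer — a
limitation shared with the underlying formulation.

Agent radii are not part of the eleven dynamics parameters and are never
stated alongside them; defaults derive from body lengths — 0.05 world units
(half a midge-like body length on the box scenarios' world scale), 0.02 m
for the metre-scaled locust scene. Static obstacles (the street lamp in the
phototaxis scene) are spheres that contribute the same constraints without
reciprocity.

## Scenarios

`build_scenario()` ships nine behaviour presets with the published
per-scenario parameter columns, radius differences converted to absolute
radii. Three columns of the source table print only the
alignment/response rows; for the missing dynamics rows the builder reuses
nearby columns and documents the choice here: the locust-migration and
phototaxis scenes reuse the bats column (large-winged fliers with the same
printed `gamma = 1.40`), and the phase-transition scene reuses the escape
column's dynamics (a midge-like swarm in the same parameter regime) with
its own schedule. The phase-transition schedule ramps `gain` linearly to
zero while ramping `chi_ali` from zero up to its column value (10.0) across
the run — turning noise down while turning alignment up — and reproduces
the disorder-to-order transition: the polarization order parameter
`|sum v_i/|v_i|| / N` rises from below 0.3 to above 0.7.

Other fixed choices the sources leave open: `dt = 1/60` s (a mocap-like
frame rate), reflecting walls for enclosed-box scenes and open boundaries
for migration and phase transition, positions initialised uniformly in the
box with zero velocities, the escape predator active for the middle third
of the run, and the bats' echolocation proxy implemented as a target
circling the cave. The temperature extension maps temperature to a
*reference* density through the published second-order polynomial (peak
~19.4 insects per unit volume near 22.2 °C, negative values clamped to zero
with a warning); closed-loop control of simulated density toward that
reference is out of scope for an agent-based model and not attempted.

The published locust figures state 2,000 insects at 34.2/m³ and 200,000 at
342/m³ "in the same space" — a 100× count against a 10× density, which is
mutually inconsistent; `measure_density()` implements only the
fixed-reference-volume convention (count / volume), under which 6× the
insects in the aggregation box give exactly 6× the density.

## Evaluation: seven metrics, discrete PDFs, entropy weights

Two swarms with entirely different positions can still be the "same kind"
of swarm. The evaluation therefore compares *distributions* of seven
kinematic metrics, one sample per insect per eligible frame: speed,
acceleration magnitude, angular velocity (`arccos` of the cosine between
consecutive velocities over `dt`, the argument clamped to `[-1,1]`, samples
with zero-speed velocities skipped), angular acceleration, Cartesian jerk
(second difference of velocity over `dt²` — the roughness proxy), nearest
neighbour distance (a density proxy), and the velocity difference
(nearest-neighbour speed minus own speed, over that distance — small for
flocks, broad for weakly aligned swarms). The velocity difference is kept
signed as defined; an absolute-value switch exists because either reading
is defensible.

Each sample set is z-scored (population SD; each dataset with its own
mean/SD, since real and simulated data live on different scales — a pooled
switch exists), then binned into `M = 50` equal sub-intervals of the pooled
sample range shared by both datasets, giving discrete densities that
integrate to one by construction. The energy of a metric is the L1
distance between the two binned densities — computed on densities as
defined, with a per-bin-probability alternative available — optionally
normalised as `(raw - p1)/p2`; the score is `E = 1 - sum w_phi E_phi`, so a
dataset compared with itself scores exactly 1. `M` and the binning interval
are the package's own defaults: the definition fixes neither.

When several models are compared, the weights come from the entropy
method: each column of the model-by-metric energy matrix is min–max
normalised (those extremes are exactly the `p1`/`p2` normalizers), turned
into a "goodness" distribution across models, and scored by its normalised
Shannon entropy; low-entropy (discriminating) metrics receive large
weights. A constant column cannot discriminate and is defined to carry
weight zero. The comparison loop alternates parameter re-estimation under
the current weights with weight recomputation until the weights move less
than `tol = 1e-3` (max absolute change) or `max_iter = 10` is reached.

## Parameter estimation

`par_est()` wraps the estimation loop: a genetic algorithm searches the
data-identifiable parameter subset — `gamma, chi_rep, r_rep, chi_att,
r_att, scale, gain` by default; alignment and stimulus-response parameters
are excluded because reference swarms without stimuli and with weak
alignment do not constrain them — maximising the evaluation score of a
candidate-parameter simulation against the reference. GA defaults
(population 30, 40 generations, tournament size 3, uniform crossover 0.8,
per-gene Gaussian mutation with sd 10% of the range at rate 0.1, one
elite) are ordinary choices for a 7-dimensional box-bounded search; none
are given by the sources. Per-parameter bounds default to `[0, 4x]` the
base value (`scale` bounded away from zero). Two deliberate deviations
from a textbook GA: every fitness evaluation simulates with one *fixed*
seed and run length, so that fitness differences reflect parameters rather
than realisation noise; and the base parameter vector is seeded into the
initial population, so `generations = 0` degrades gracefully to "evaluate
the base model". Estimated radii are repaired against the fixed `r_ali`
(`r_rep <- min(r_rep, r_ali)`, `r_att <- max(r_att, r_ali)`) to keep the
zone ordering valid, which can push `r_att` above its nominal upper bound —
the repair is reported, not hidden. Elitism makes the best-so-far fitness
trace non-decreasing, which is tested.

## The synthetic reference generator

Real midge/fruit-fly mocap recordings are the intended reference inputs
(frame-indexed 3D positions at fixed `dt`, which `read_trajectory()`
accepts as plain text), but they cannot be redistributed here.
`generate_fixture()` therefore stands in:

* `swarmlike` — a full dynamics + curl-noise run: 50 insects, 300 frames at
  `dt = 1/60` in a 10-unit reflecting box, `gamma = 2`, `scale = 1`,
  `gain = 2`, `chi_rep = 2` / `r_rep = 0.3`, no alignment, `chi_att = 6` /
  `r_att = 4`. These values were chosen once to emulate the structure of a
  laboratory midge swarm — bounded, noisy, weakly aligned, with a clear
  attraction-noise balance — at a desk-scale problem size.
* `lattice`, `straightline`, `two_body` — analytic trajectories whose
  metric values are known in closed form, used as unit-test oracles.

What the synthetic generator does *not* emulate: measurement noise and
tracking gaps, insect-count fluctuation across frames, boundary-layer
behaviour near real enclosure walls, and any species-specific kinematic
signature. Consequently the recovery and ablation experiments show that
the estimation machinery works — the pipeline discriminates the generating
model class from its ablations and recovers score-equivalent parameters —
not that the model is a validated description of any particular species.
Score-equivalence is also the honest statement of what the GA recovers:
with seven partially confounded parameters and distribution-level fitness,
distinct parameter vectors can score alike (the fitted score frequently
*exceeds* the generating parameters' score on a finite reference
realisation), so assertions are on scores, not on parameter values.

## Problem sizes and reproducibility

The shipped experiments use desk-scale sizes chosen as the package's
standard test conditions: recovery runs a 50-agent, 300-frame fixture with
a population-10, 4-generation GA over 150-frame candidate simulations
(5 GA seeds); the ablation comparison uses 30-agent, 200-frame references
with `generations = 0` populations of 4 (the base parameters seeded first)
and two weight iterations; the collision contract runs 100 agents for 500
steps; the phase transition 60 agents for 400 frames. Every stochastic
component — initialisation, noise, GA, escape angles — draws from seeded
streams, and `simulate_swarm()` restores the caller's RNG state, so every
result in the tests and the acceptance script is bit-reproducible from the
stated seeds on one platform.

## Known limitations

Adult flying insects only: no walking, swimming or eusocial behaviour, no
wing aerodynamics or morphology. The GA is probabilistic and may return
local optima; scores, not parameters, are the reliable output. Density is
an emergent property — it cannot be servo-controlled to the
temperature-derived reference. The avoidance operator's guarantee applies
to the feasible regime; deliberately infeasible crowding degrades to
stopped agents. And the entropy-weighted score is relative to the models
in the comparison: it ranks candidates against a reference, it does not
certify absolute realism.
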