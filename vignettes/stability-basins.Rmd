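---
title: "Stability Basins for Sit-to-Stand: models, fitting, and evaluation"
author: "StabilityBasin package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability Basins for Sit-to-Stand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(StabilityBasin)
```

## The problem

Rising from a chair is one of the motions most strongly associated with fall
risk, and it is aperiodic, so the classical stability measures for gait
(Floquet multipliers, Lyapunov exponents) do not apply. This package
quantifies the stability of an individual's Sit-to-Stand (STS) movement as a
*Stability Basin*: the set of body states, indexed over the progress of the
motion, from which the person can still reach standing **without abandoning
their chosen movement strategy** (abandonment being observable as a step or
as sitting back down). A recorded trial whose state leaves the basin at any
time is predicted to end in a step or sit; a trial that stays inside is
predicted successful.

## The model

The body is reduced to a telescoping inverted pendulum: a point mass $m$ at
the centre of mass (COM) in the sagittal plane, with state
$x = (r_x, v_x, r_y, v_y)$ (anterior–posterior and vertical COM position and
velocity, origin at the initial ball of the foot) and a two-component force
input $u = (u_x, u_y)$:

$$\dot x \;=\; \bigl(v_x,\; (u_x + d_x)/m,\; v_y,\; (u_y + d_y)/m - g\bigr),$$

where $d$ is the external (cable-pull) disturbance force and
$g = 9.81\,\mathrm{m\,s^{-2}}$. Because trial durations vary, every trial is
mapped to the dimensionless time $t = \tau/T \in [0,1]$ (0–100 %STS):
velocities are multiplied by $T$ and accelerations and forces by $T^2$
(`normalizeTrial()`). The basin dynamics need a single time scale for the
gravity term; we use $\bar T$, the mean duration of the strategy's nominal
trials, stored in `tipmParams()`. Per-trial inverse dynamics
(`inverseDynamics()`) uses each trial's own $T$:
$u_x = m a_x - d_x$, $u_y = m(a_y + g T^2) - d_y$.

## Controller models

All three controller models are fitted per subject and strategy from the
*successful* trials only (nominal, foot-shift, and successfully recovered
perturbed trials), with samples inside a perturbation window masked out —
the inputs recovered there reflect the cable, not the subject.

* **LQR** (`fitLqr()`): linear feedback about the average nominal trajectory,
  $u(t,x) = u_{ol}(t) - K(t)\,(x - \bar x(t))$. The gains come from a
  finite-horizon discrete-time Riccati recursion (zero-order hold,
  $\Delta t = 0.005$, terminal cost $P(1) = Q$) with diagonal weights chosen
  to best reproduce the observed inputs. The weight boxes are
  $Q_{11} = 1$, $Q_{22},Q_{33},Q_{44} \in [0.1, 100]$,
  $R_{11} \in [10^{-5}, 10^{-2}]$, $R_{22} \in [10^{-6}, 10^{-1}]$; they pin
  relative state/input costs. Because the point-mass dynamics, the diagonal
  weights and the squared-error objective all decouple into the horizontal
  and vertical 2×2 subsystems, the optimiser factorises the 5-dimensional
  box search into a 2-D and a 3-D grid (5 log-spaced points per axis)
  followed by a joint Nelder–Mead refinement clipped to the box. The search
  is fully deterministic. Note the per-axis weight scale is not identified —
  scaling $(Q, R)$ of one axis jointly leaves the gain unchanged — so fitted
  weights are only meaningful up to that scale; the gains are what matter.
* **FF+FB** (`fitFfFb()`): per time step, the linear least-squares fit
  $u_i(t) \approx f\!f(t) - K(t) x_i(t)$ over valid samples.
* **Input Bounds** (`fitInputBounds()`): the proposed set-valued model
  $u(t,x) \in [\,b_{lb}(t) - K(t)x,\; b_{ub}(t) - K(t)x\,]$. Per time step
  and input component, a constrained least-squares quadratic program places
  the tightest band (shared feedback row, separate lower/upper offsets) that
  still contains **every** observed input — a hard constraint. The two input
  components decouple, so each solve has 6 unknowns. Coincident states
  (every trial starts from the same seated posture) would duplicate
  constraint rows and stall the active-set solver, so only the extreme input
  per distinct state enters the constraint set; the objective keeps all
  samples.

**Conditioning.** The per-step state clouds of STS trials are nearly
rank-one (trials bundle tightly around the strategy's path), so an
unpenalised regression can return feedback gains of order $10^6$, which
overflows the matrix exponential of the closed loop downstream. Both
regression-based fits therefore carry a ridge penalty on the feedback
entries, default `1e-4` scaled to the state magnitudes. This is a
conditioning device, not a modelling choice: it caps gains around $10^4$,
far above anything biomechanically meaningful, and leaves well-conditioned
fits untouched (the exact-recovery tests in the suite use a ridge of
$10^{-10}$ and recover generating controllers to $10^{-6}$).

## Computing the basin

The target set $X_T$ (`buildTargetSet()`) is an oriented-box zonotope with
four generators around the successful trials' states at $t = 1$, each
generator expanded by 5% so observed states do not sit exactly on the
boundary. It represents "states observed to lead to standing", not quiet
standing.

A zonotope $Z = \{c + G\beta : \|\beta\|_\infty \le 1\}$ is closed under
linear maps and Minkowski sums, which makes the backward recursion exact for
linear closed loops: with the closed-loop matrix $A_{cl} = A - BK(t)$ frozen
at each step midpoint,

$$Z^{(t-\Delta t)} = e^{-A_{cl}\Delta t} Z^{(t)} \;\oplus\; \Gamma\,(-W(t)),
\qquad \Gamma = \sum_{k=0}^{10} (-A_{cl})^k \frac{\Delta t^{k+1}}{(k+1)!},$$

where $W(t)$ is the affine input-effect set: a singleton for LQR and FF+FB,
and the image of the input box (two generators per step) for Input Bounds.
`computeBasin()` runs 200 such steps of length $\Delta t = 0.005$ from
$X_T$ down to $t = 0$ and stores one zonotope per grid point. Generators are
capped at 800 by box-based order reduction (`reduceOrder()`: the generators
with the smallest $\|g\|_1 - \|g\|_\infty$ score are replaced by their
interval hull, an outer approximation); with two generators added per step
the cap never binds here, but it guards pathological fits. The truncation
order 10 of $\Gamma$ leaves a remainder many orders below solver tolerances
at $\Delta t = 0.005$. The basin is computed with zero cable-pull
disturbance: perturbations are features of individual trials, not of the
strategy's dynamics, and perturbed segments are already excluded from
training.

The **naive** baseline (`computeNaiveBasin()`) simply wraps the observed
successful states at each time step in the same oriented-box construction
(including the 5% expansion), using no dynamics at all.

## Checking trajectories

Membership of a state in a slice is decided by the linear program
$\min \beta_{max}$ s.t. $G\beta = x - c$, $|\beta| \le \beta_{max}$
(`containsPoint()`); the point is inside iff $\beta_{max} \le 1$, with a
relative boundary tolerance of $10^{-9}$ so target-set boundary points
classify as inside. Numerical choices worth knowing:

* No general LP solver is available to the package at run time, so the
  program is solved by a dense revised simplex written for this purpose
  (split-variable standard form, big-M artificials, Bland's-rule
  anti-cycling, periodic refactorisation), validated in the test suite
  against an exact polygon oracle on tens of thousands of random queries.
* If $x - c$ has a component outside the column space of $G$ (least-squares
  residual above tolerance) the point is declared outside with
  $\beta_{max} = \infty$ rather than relying on LP infeasibility detection.
* Rows of $[G \mid x - c]$ are equilibrated before solving: strongly
  contracting closed loops produce slices whose generator rows span many
  orders of magnitude, and row scaling (which leaves $\beta$ unchanged)
  keeps the rank test and the LP meaningful there.
* During trial classification (`classifyTrial()`), certified bounds can
  short-circuit the LP: a feasible representation (minimum-norm
  least-squares) bounds $\beta_{max}$ from above, support-function
  evaluations bound it from below. The inside/outside decision is exact
  either way; `exact = TRUE` forces the LP when the exact coefficient is
  wanted.

Classification follows the evaluation protocol: for cable-pull trials only
the portion of the basin after perturbation onset is used, and for failed
trials only the portion before failure onset $t_f$ (afterwards the subject
has already abandoned the strategy); window endpoints snap outward to whole
slices. Failure onset is a step (toe displacement strictly greater than
0.0762 m from its start) or a sit (horizontal and vertical COM velocity
simultaneously negative), whichever is earlier; onsets after the defined
trial end keep the unsuccessful label with $t_f$ clamped to 1. Sit detection
requires the sign condition to persist for 3 consecutive samples — a
debounce for numerical noise; it is configurable and the detectors are pure
functions, so other choices are easy to audit.

The leave-one-out protocol (`leaveOneOutEvaluate()`) refits the controller
(or the naive slices) without each successful trial before classifying it;
unsuccessful trials are classified against the basin built from all
successful trials. The target set is deliberately **never** refit under
leave-one-out: hull-edge trials would otherwise be misclassified by
construction.

## The synthetic experiment generator

No public STS dataset with perturbation outcomes exists, so the package
ships a generator (`generateDataset()`) that emulates the perturbative
protocol for one subject and makes every pipeline stage testable against
known ground truth. Per strategy it produces 5 nominal trials, 6 foot-shift
trials (initial COM offsets in ±0.05 m increments) and 18 cable-pull trials
(three force levels × forward/backward), matching the experimental design
the method was developed for. Strategy-level defaults are the reported
cohort statistics: durations 1.25 ± 0.23 s (natural), 1.13 ± 0.21 s
(momentum transfer), 2.23 ± 0.89 s (quasi-static); perturbation onset
0.50 ± 0.10 of the trial; subject mass 65.4 kg.

Each trial tracks a minimum-jerk seat-to-stand COM path (strategy-specific
horizontal shaping gives the characteristic acceleration ordering
quasi-static < natural < momentum-transfer) under a ground-truth bounded
controller: nominal input, plus smooth trial-to-trial input noise, plus PD
recovery feedback, with the noise-plus-feedback term saturated inside a
fixed band $\pm W$. Because the saturation applies to the whole deviation
term, the total input provably stays inside $u_{nom} \pm W$ — the generating
controller *is* an input-bounds controller (with zero explicit feedback in
the bound parametrisation), and successful trials' inputs lie inside the
band by construction. Failures are mechanistic: when a cable pull demands
recovery beyond the band for long enough, the horizontal deviation crosses
an abandonment threshold and the simulated subject steps (forward, with a
toe-swing proxy trajectory) or sits back (backward, with a descending
target); outcome labels then come from the package's own step/sit detectors
applied to the simulated series, never from the trigger itself.

Details that matter and their rationale:

* **Trial segment**: the defined trial covers 90% of the full path
  (`endFraction`), so end-of-trial velocities remain positive, as they do
  after real segmentation (observed step onsets can fall after the defined
  end). Without this, the sit rule fires spuriously on terminal settling,
  where the nominal velocity passes through zero. Failure detection runs
  25% past the trial end (capped before full path deceleration), and onsets
  past $t = 1$ are clamped, mirroring the evaluation convention.
* **Cable pull**: a half-sine force pulse of 150 ms. The three peak levels
  (1.6, 2.4, 2.8 m s⁻² × mass) were calibrated the way the original
  protocol prescribes for its hardware: the low level rarely induces
  failure, the high level does so about half the time. At the default seed
  the perturbed-trial failure fraction is ~32%, with sits from backward and
  steps from forward pulls.
* **Input noise**: per-trial smooth profiles (three random harmonics) with
  amplitude drawn from 0.15–1.05 of the band half-width and an
  endpoint-vanishing envelope $\sin^2(\pi t)$. The envelope makes trials
  converge tightly to standing (keeping the target set small, as in real
  data, where everyone ends standing); its flip side is that the band the
  controller *exercises* is the envelope-scaled band, which is what
  `groundTruthBounds()` reports and what the fitted bounds converge to.

What passing tests on these data do and do not show: the generator produces
a single point-mass "subject" whose inputs really are band-bounded, whose
noise is smooth and low-dimensional, and whose failures follow a sharp
deviation threshold. Real trials have marker noise, richer within-trial
input structure, multi-segment dynamics projected onto a point mass, and
fuzzier failure behaviour. The suite therefore validates the machinery
(set computations exactly; fitting against known ground truth; the
evaluation protocol end-to-end) and the qualitative method ranking, not the
human-data accuracy percentages.

## What the end-to-end comparison shows

On the default synthetic dataset, the leave-one-out evaluation reproduces
the method ranking that motivates the set-valued controller: the Input
Bounds basin classifies the large majority of successful trials correctly
while the LQR, FF+FB and naive basins — all of which collapse the observed
input variability to a single trajectory bundle — predict failure for most
successful trials (their basins underapproximate the stable region, visible
as false step/sit prediction rates several times higher). Dilating the
three underapproximating basins by 5% or 25% improves their success rates
monotonically but does not close the gap. The acceptance script
(`scripts/acceptance.R`) recomputes all of these rates from scratch.

## Known limitations

* The closed-loop propagation freezes gains at step midpoints; for the
  time-varying fitted controllers this is $O(\Delta t^2)$ per step, far
  below the 5% target-set expansion, but it is not a certified enclosure.
* The containment LP is exact but not warm-started; classification of an
  input-bounds basin costs a few LP solves per slice with hundreds of
  generators. Certified-bound short-circuiting keeps this to seconds per
  trial.
* One subject, one session: the generator models within-strategy
  variability, not between-subject morphology differences; `mass` and the
  path geometry are single parameters, not a population model.
* Strategy labels are taken as given; mislabelled strategies (a real
  phenomenon — subjects sometimes switch mid-session) would blur fitted
  bounds exactly as in the human experiment.
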