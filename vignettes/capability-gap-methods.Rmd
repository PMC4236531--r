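---
title: "Methods: capability-gap analysis with costly reserve actuators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: capability-gap analysis with costly reserve actuators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capgap)
```

## The model and its assumptions

`capgap` estimates the assistive joint moment a weakened user needs during
activities of daily living (ADL) by letting a musculoskeletal model attempt
the task and measuring what its muscles cannot deliver.  The model is a
planar sagittal open chain — thigh, shank, foot hanging from a fixed hip —
with three degrees of freedom (hip, knee, ankle flexion/extension; extension
and plantarflexion positive) and nine lumped Hill-type muscle groups.  Three
of them (hamstrings, rectus femoris, gastrocnemius) are bi-articular, which
is what couples the capability of adjacent joints: a gap at the ankle depends
on what the gastrocnemius is simultaneously asked to do at the knee.

Assumptions worth stating explicitly:

* **Active force only, rigid tendon.**  Muscle force is
  `a · F⁰ · f_L(l̃) · f_V(ṽ)`; passive fiber force and tendon compliance are
  excluded, and fiber length change equals musculotendon path length change
  (the integral of the moment arm over joint angle, computed exactly from the
  moment-arm polynomials).  With a rigid tendon the fiber sees the whole
  joint excursion, so the *operating* optimal fiber lengths of the lumped
  groups are longer than anatomical fascicle lengths and each group's
  `optimal_angle` places `l̃ = 1` in the posture range where its demand
  peaks.
* **Instantaneous control.**  Frames are solved independently; there is no
  activation dynamics and no rate coupling.  This is what makes the
  optimization a per-frame convex program.
* **Kinematics do not adapt.**  The same trajectories are tracked at every
  weakness level; the user is assumed to accept the assistive moment without
  changing strategy.
* **Sagittal plane only.**  Non-sagittal hip function is out of scope.

The force–length curve is a Gaussian, `f_L(l̃) = exp(−((l̃−1)/0.45)²)`.  The
force–velocity curve is the classic Hill hyperbola for shortening (zero force
at the maximal contraction velocity, default 10 optimal lengths/s) joined at
the isometric point, with matched value and slope, to a saturating eccentric
branch with plateau 1.4.  Both equal 1 at the isometric optimum, so active
force is exactly linear in activation and in maximal isometric force — which
is also why uniform weakness (`apply_weakness`) scales every muscle's whole
force surface by `1 − w`.

Grouped maximal isometric forces follow a widely used generic lower-limb
model (e.g. soleus 5137 N, vasti 4530 N), with the gluteal group set to
2400 N to represent all hip extensors.  Moment arms are low-order polynomials
in the spanned joint angle only.

## The static optimization and the reserve actuators

Each frame solves

$$\min_{a}\; \sum_t a_t^2 + \sum_m a_m^2
\quad\text{s.t.}\quad
\tau_k = \sum_t \tau^0_{t,k}\,a_t + \sum_m a_m\, f(F^0_m, l_m, v_m)\, r_{m,k},
\qquad 0 \le a_m \le 1,$$

with one unbounded reserve (ideal moment actuator) per DOF and
`τ⁰ = 1 Nm`.  Design choices here were genuinely open and are resolved as
follows:

* **Reserves are unbounded and enter the objective exactly like muscles.**
  This is the only reading under which a 1 Nm optimal moment makes them
  "costly" (their activation equals their moment in Nm) while still able to
  bridge arbitrarily large deficits, guaranteeing feasibility of every frame.
* **The moment constraint is an equality**, and muscle activations are hard
  bounded at 1: the gap concept requires saturation, not penalties.
* **Measured fiber velocity enters f_V.**  The alternative (isometric
  `f_V ≡ 1`) would overestimate capability precisely during the fast
  push-off phases where gaps matter most.

Because the objective is strictly convex the solution is unique; no
tie-breaking is needed.  The reserves are eliminated exactly through the
equality constraints, leaving a bound-constrained quadratic program in the
muscle activations that a small active-set solver (`solve_box_qp`) solves to
machine precision; the moment constraint then holds exactly by construction.
`kkt_residual()` certifies stationarity (typical residuals `< 1e-8`), and
`brute_force_oracle()` provides an independent grid-enumeration check.  The
oracle enumerates the full activation grid when it is small enough and
otherwise refines a coarse grid locally, which is valid because the
eliminated objective is convex; its optimum converges to the QP optimum from
above as the grid step shrinks, with a second-order error term
`(gain · step)²/τ⁰²` that dominates the naive first-order estimate whenever
gains are large — the reason the oracle cross-checks in the tests use
desk-scale gains.

### The reserve leak and the gap-detection threshold

A quadratic-cost reserve never carries exactly zero moment: splitting a
demand `τ` between a muscle gain `g` and a reserve `τ⁰` leaves the reserve
with `τ·τ⁰²/(g² + τ⁰²)` — order 1e-4 Nm/kg for healthy gains.  "A gap is
present" therefore needs a cutoff; the default threshold is **0.01 Nm/kg**
(≈1 Nm for a 100 kg user), configurable everywhere it is used.  Two
consequences are documented rather than hidden:

* Below the threshold the leak fluctuates with posture and is not
  sign-constrained, so frame-wise gap monotonicity across the weakness sweep
  is only guaranteed above the threshold; sub-threshold wiggles stay about an
  order of magnitude below it.
* The weakness tolerance (`tolerance_level`) is the first sweep level whose
  gap exceeds the threshold, so it is quantized to the sweep step (10%) and a
  planted demand of `ratio × capability` is recovered at `1 − ratio` within
  one step.

## The synthetic ADL generator

No subject data ships with the package; `generate_trial()` builds trials
whose statistical structure matches what the analysis assumes.  Joint angles
are closed-form — truncated Fourier series for the cyclic activities (gait,
stair ascent/descent), logistic transitions for sit-to-stand/stand-to-sit —
so velocities and accelerations are exact derivatives, and cyclic trials
close on themselves to machine precision.  Net moments are authored as sums
of Gaussian bumps over the cycle (Nm/kg), with peaks set to magnitudes
reported for healthy adults (ankle plantarflexion 1.68 Nm/kg in stair ascent
down to ≈0.1 Nm/kg dorsiflexion in gait).

Dynamic consistency is enforced by construction rather than by scaling a
canned ground-reaction profile: for every frame the generator solves the
3×3 linear system in `(F_x, F_y, x_{cop}·F_y)` for the unique planar point
ground reaction under the foot that, together with gravity and the segments'
inertial loads, reproduces the authored moments on the chain.  Re-running
`inverse_dynamics_planar()` on the stored kinematics and load therefore
returns the stored net moments to machine precision — the property the test
suite asserts.  The system is singular only when hip, knee and ankle are
collinear (a fully straight leg), so the fixture profiles keep at least
≈0.1 rad of knee flexion.  Two honest limitations follow: the center of
pressure is unconstrained and can leave the anatomical foot when the vertical
force is small (swing-like phases), and the hip is inertially fixed, so
pelvis translation dynamics are absent.  Neither affects the downstream
analysis, which consumes only angles, velocities and moments.

Trial-to-trial variability (`noise_sd`) perturbs the harmonic and bump
amplitudes multiplicatively under a seed; replicate synthetic trials stand in
for the across-subject spread of an experimental cohort.  What the generator
does **not** emulate: measurement noise in kinematics, soft-tissue artifact,
real GRF waveforms, or any adaptation of strategy to weakness — so passing
tests demonstrate correctness of the pipeline on well-posed inputs, not
robustness to the pathologies of real motion-capture data.

The fixture kinematics were calibrated once, before the test suite was
frozen, to two contracts: the full-strength model must meet every shipped
demand (no detected gap at `w = 0`), and the weakness tolerances must
reproduce the ordering and approximate levels reported for healthy adults —
stairs (30%) < gait (40%) < sit-to-stand (60%) < stand-to-sit (80%) on the
shipped fixtures, the stair tasks failing first through ankle
plantarflexion.  The main calibration lever is physiological: how much
shortening velocity and fiber-length excursion the plantarflexors see at the
moment peak.

## EMG validation chain

`generate_emg()` produces an amplitude-modulated broadband carrier
(20–400 Hz, unit RMS, 1000 Hz sampling) whose envelope is the simulated
activation, plus additive broadband noise.  `process_emg()` applies the
standard envelope pipeline in exactly this order: zero-lag 4th-order
Butterworth band-pass 20–400 Hz, full-wave rectification, zero-lag 4th-order
Butterworth low-pass 10 Hz, normalization to the trial maximum, resampling to
the trial frames.  Forward–backward filtering uses odd-reflection padding of
half a second so start-up transients decay inside the pad; without it a DC
input leaks ≈10% into the envelope at the edges.  Since the validation
statistic (`spearman_validation`, average ranks for ties, seeded permutation
p-value) is rank-based, the normalization choice cannot affect the reported
correlation.  With zero noise the closed loop recovers a well-recruited
muscle's activation at ρ ≥ 0.95 (finite-filter smoothing prevents exactly 1,
and muscles that are silent for much of the cycle rank lower — which is also
why experimental validation tables report weaker correlations for
intermittently recruited muscles); correlations degrade as the noise level
grows.

## Numerical choices and problem sizes

* QP: exact active-set on matrices of at most 9 muscles × 3 DOFs; bound /
  stationarity tolerances 1e-11; failures raise errors with the frame index,
  never silent.
* Shipped trials: 100 Hz kinematics, 1.1–2.4 s per activity (111–241 frames);
  a full 5-activity × 11-level sweep is ≈9000 QP solves and runs in a couple
  of seconds.  Reporting resamples to 101 cycle points; computation stays at
  native sampling.
* Differentiation: central differences, one-sided at the ends, optional
  zero-lag low-pass (default off; 6 Hz conventional for mocap when enabled).
* Degenerate inputs: non-finite kinematics, non-positive fiber lengths,
  constant series in the Spearman statistic, and sampling rates below twice
  the band-pass edge are errors, not warnings.

## Known limitations

Joint stabilization demands, fatigue, antagonistic co-contraction strategies,
mass changes with weakness, and kinematic adaptation are all outside the
model; the tolerance levels are therefore optimistic for populations that
adapt their strategy.  The cost function fixes the muscle-force distribution
but has limited influence on the gap itself, which is bounded by saturated
muscle capability; per-DOF reserve costs (`reserve_optimal_moment`) are
exposed for actuator-cost trade-off studies but no optimization loop over
them is provided.
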