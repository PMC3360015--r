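---
title: "A population-vector model of motor-cortex reorganization under bimanual rehabilitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A population-vector model of motor-cortex reorganization under bimanual rehabilitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`bimanrehab` simulates a directionally tuned motor-cortex population
performing center-out reaches, damages it, and rehabilitates it by
trial-by-trial gradient learning. The question the package is built to
ask is: *which feature of bimanual movement makes bimanual
rehabilitation reorganize a damaged map when unimanual rehabilitation
does not?*

**Tuning.** Neuron $i$ carries a preferred direction (PD) $\phi_i$ and a
modulation depth $d_i$. For a reach toward target angle $\theta$ its
mean activity is a rectified cosine,

$$a_i(\theta) = \left[\, d_i \cos(\theta - \phi^{enc}_i) \,\right]_+ ,$$

where $[\cdot]_+$ is rectification at zero and $\phi^{enc}_i$ is the
neuron's *encoding* PD for the current movement condition. Activity is
corrupted by signal-dependent noise: zero-mean Gaussian with variance
$k \, a_i$, re-rectified at zero, so silent neurons stay exactly silent.

**Decoding.** The reach is modeled by the population vector

$$\mathbf{PV}(\theta) = \frac{1}{N} \sum_{i\ \mathrm{alive}} a_i \,
\big(\cos\psi_i, \sin\psi_i\big),$$

where $\psi_i$ is the *decoding* PD (the cortical-spinal-muscle
readout direction) and $N$ is the **original** neuron count. The PV
angle models reach direction and its norm models reach speed. Dividing
by the fixed pre-lesion $N$, rather than by the surviving count or the
summed activity, is what lets a lesion slow the modeled reach: the same
denominator now divides less activity. This choice follows from the
model's target phenomenology — the post-stroke speed deficit — and it
has a hard consequence discussed under *Limitations*.

**Lesion.** A stroke is a wedge depletion: every neuron whose base PD
lies within $d \cdot 180^\circ$ of the lesion center (default
$90^\circ$, fraction $d = 0.25$) has `alive` set to `FALSE`. Dead
neurons contribute no activity and are never updated.

**Movement conditions.** Unimanual movement leaves tuning untouched and
sets $\psi_i = \phi_i$. Bimanual movement perturbs tuning; the package
implements the candidate perturbations as separate regimes so their
effects can be isolated:

* `bimanual_quenched` — encoding PDs are rotated by per-neuron offsets
  $\delta_i \sim \mathcal{N}(0, \sigma^2)$ drawn once and frozen
  ("quenched"); decoding PDs are *not* rotated.
* `bimanual_annealed` — the same rotations redrawn every trial.
* `bimanual_depth_only` — depths are scaled by quenched factors
  $\exp(\mathcal{N}(0, \sigma_d^2))$; no PD rotation. The lognormal
  form keeps depths positive; the literature this model draws on states
  only that depth differs between conditions, not how.
* `bimanual_enc_dec` — encoding *and* decoding PDs rotated together.

The mechanistic account of *why* bimanual movement rotates encoding
PDs is inter-hemispheric inhibition: right-hemisphere neurons, active
during bimanual movement, drive interneurons that subtract
cosine-tuned input $-c\cos(\theta - \rho_k)$ from a left-hemisphere
neuron's drive. A sum of equal-frequency cosines is again a cosine
(`cosine_sum()`), so the effective tuning keeps its shape but its peak
shifts — an effective encoding-PD rotation (`inhibition_rotation()`).
With sparse callosal connectivity (small $K$) the rotations are random
across neurons and grow with $c$; with dense connectivity the
inhibitory phases average out by the law of large numbers and the
rotation vanishes. We treat a resultant rotated by $90^\circ$ or more
as degenerate (net drive along the original PD is no longer positive)
and report it rather than clipping.

**Learning.** Rehabilitation minimizes, per trial,

$$C = e^2 + \lambda \sum_i a_i^2,$$

where $e$ is the wrapped angular error (degrees, in $(-180, 180]$)
between the PV and the target — the supervised term — and the second
term is the metabolic (unsupervised) cost of the trial's activities.
The base PDs of alive neurons descend this cost with separate rates:

$$\phi_i \leftarrow \phi_i
  - \eta_{sup} \frac{\partial e^2}{\partial \phi_i}
  - \eta_{unsup} \frac{\partial \lambda \sum a^2}{\partial \phi_i}
  + \xi_i, \qquad \xi_i \sim \mathcal{N}(0, \sigma_{drift}^2),$$

with the gradient evaluated at the trial's *sampled* activities — the
learner sees the same noise realization that produced the movement.
Quenched offsets, depths, and dead neurons are never updated.

## The gradient path: a design decision forced by the dynamics

Because decoding PDs are yoked to the base PDs ($\psi_i = \phi_i$ plus
a fixed offset in the enc+dec regime), moving $\phi_i$ changes both the
neuron's activity *and* its readout direction. The full gradient
therefore has an encoding-path term (through $a_i$) and a
decoding-path term (through $\psi_i$), and only their sum is a descent
direction for $C$.

We initially considered updating through the encoding path alone, on
the argument that reorganization acts on motor planning. That variant
is kept as `update_targets = "encoding_only"` for sensitivity
analysis, but it cannot be the default: dropping the decoding-path
term makes unimanual rehabilitation *increase* movement error in
simulation (the update is not a descent direction), and noiseless
fixed-target descent fails. The default
`update_targets = "encoding_and_decoding"` is the exact gradient; the
test suite verifies it against central finite differences and verifies
monotone cost descent in the noiseless case.

At the rectifier kink we use subgradient 0: a neuron whose drive is
non-positive receives no supervised gradient that trial. A zero-norm
PV has an undefined angle; its error is scored as the maximal
$180^\circ$ so a silent population still registers failure, and the
supervised gradient is zeroed for that trial (the angle derivative does
not exist there).

## Defaults and why

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `population.n` | 500 | neurons; large enough for a smooth map, small enough for fast trials |
| layout | equally spaced | deterministic tests; i.i.d. uniform available |
| depth | 1 | single depth scale; amplitude conventions beyond this add nothing to the questions asked |
| lesion center, fraction | 90°, 0.25 | a quarter-circle wedge straight ahead |
| `condition.sigma` | 60° | "strong" rotation; the regime where bimanual rehabilitation equalizes best |
| `noise.k` | 0.1 | signal-dependent noise strength; trial-to-trial PV jitter of a few degrees |
| `learning.eta_sup`, `eta_unsup` | 0.05 | chosen once by pilot grid (0.01–0.5) as the smallest rates at which reorganization is clearly visible within 1000–3000 trials and errors fall in both unimanual and bimanual courses; larger rates blur the unimanual/bimanual contrast because the step noise itself starts acting as search noise |
| `learning.lam` | 0.01 | metabolic weight; supervised term dominates, as the recovery phenomenology requires |
| `drift.sigma` | 1°/step | "moderate" synaptic drift for the drift scenario; a random walk of this size explores tens of degrees over 3000 trials |
| `protocol.n_trials` | 3000 | snapshots at 1000/2000/3000 |
| targets | 0°, 45°, …, 315° | the 8 standard center-out targets, uniform draw |
| `metrics.n_bins` | 36 | 10° histogram bins |
| `metrics.n_reps` | 200 | evaluation repetitions per target |

Angles are degrees at every interface (wrapped to $[0, 360)$ for PDs,
$(-180, 180]$ for differences) and radians only inside trigonometric
calls.

## Reorganization metrics

Histograms of alive base PDs are the primary readout, summarized by two
scalars so claims become testable: **uniformity**, the Shannon entropy
of the 36-bin distribution normalized by $\log 36$ (1 for a perfectly
equalized map), and **wedge fill**, the fraction of alive neurons whose
base PD lies inside the original lesion wedge (0 immediately
post-lesion; 0.25 for a fully equalized map with a quarter-circle
lesion). Behavioral readouts (`evaluate_unimanual()`) are per-target
mean absolute angular error and mean PV norm with Monte-Carlo standard
errors — rehabilitation happens under a movement condition, but
assessment is always unimanual reaching.

Scenario contrasts are paired by seed: the base population, lesion,
target sequence, and noise stream are shared, so a difference between
two scenarios isolates the manipulated factor.

## What the simulations show — and what they cannot

The test suite establishes, at the defaults above: quenched encoding-PD
rotations refill the lesion wedge beyond the unimanual baseline in
paired runs; depth-only changes and joint encoding+decoding rotations
do not; the refilling is driven by the supervised term (it survives
`eta_unsup = 0` and disappears under `eta_sup = 0`); Gaussian synaptic
drift reorganizes without any rotation; and inhibition-induced rotation
spread grows with inhibition strength under sparse connectivity while
vanishing in the dense limit.

One documented divergence: in this implementation, *annealed* (redrawn
every trial) rotations also reorganize the map — roughly as strongly
as quenched ones. The mechanism is a ratchet through the supervised
term: whenever a rotation happens to activate a neuron whose decoding
PD is far from the current target, the gradient pulls that neuron
toward reducing the error, and these pulls accumulate toward the
depleted region even though the rotations average to zero. The
corresponding acceptance check (annealed rotations leaving the wedge
no fuller than unimanual rehabilitation) is expected to fail and is
deliberately left failing rather than weakened; settling whether the
ratchet is a genuine property of this model class or an artifact of the
cost form is future work.

Two further geometric facts constrain what "recovery" can look like
here. First, the default lesion is mirror-symmetric about a target
(90°), so the mean PV at that target points *at* the target and the
largest angular errors sit at the wedge-edge targets (45°/135°) — the
deficit at the center shows up in the norm (speed), not the mean
direction. Second, neuron count is conserved, so any refilling of the
wedge necessarily thins PD density elsewhere; under fixed-$N$
normalization the PV norm at far targets must drop as the map
equalizes (from 0.25 toward the uniform value of about 0.19 with a
quarter lesion). A model in which far-direction speed is exactly
preserved while the wedge refills would need depth growth or
renormalization, both outside this model's assumptions.

## What the generator emulates, and what it does not

The synthetic population stands in for a motor-cortex map: uniform PD
coverage, cosine tuning, signal-dependent noise, and a contiguous
directional lesion. It does not emulate spiking dynamics,
within-reach trajectories, biomechanics (muscle geometry determining
decoding PDs), retention after rehabilitation ends, or the right
hemisphere's own plasticity. Passing tests therefore support claims
about the population-vector model class, not about patients;
in particular the lesion is perfectly sharp and the map perfectly
uniform pre-lesion, both idealizations.

## Numerical choices

* Quenched draws are pure functions of `(n, sigma, seed)`; quenched
  rotations, depth factors, the trial stream, and evaluation draws use
  separate named seeds so experiments are independently reproducible.
* The finite-difference gradient mode holds the trial's noise
  realization fixed (recovered additively from `activity - mean`) and
  respects the configured gradient path; its default step is
  $10^{-5}$ degrees. Verification tests use a $10^{-4}$ step, which
  keeps the difference quotient above roundoff on costs of order
  $e^2 \approx 10^4$.
* `cosine_sum()` flags resultants below $10^{-12}$ of the summed
  amplitudes as undefined rather than returning a roundoff-scale phase.
* A nonfinite learning step rejects the trial (population unchanged,
  trial logged) instead of propagating.
* Histogram binning guards the `360 - eps` edge case by clamping into
  the last bin.

## Problem sizes

Simulation-based tests run the full study conditions (500 neurons, 3000
trials) with 5–10 paired seeds per contrast; evaluation repetitions are
trimmed to a handful except where standard errors are themselves under
test (200 per target). Oracle tests use populations of 3–15 neurons
with 100 random instances per primitive.
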