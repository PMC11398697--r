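---
title: "Nonlinear normal modes and resonant excitation of a compliant double pendulum: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlinear normal modes and resonant excitation of a compliant double pendulum: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, numerical choices and design decisions
behind `pendmode`. The package reproduces, in simulation, a rhythmic
human-machine interaction paradigm: a person (here, a synthetic stand-in)
drives a horizontally swinging, elastically jointed double pendulum through
a commanded *motor link* and must alternately hit two targets with the
pendulum tip. The scientific backbone is the system's *nonlinear normal
modes* (NNMs): energy-parametrized families of rest-to-rest periodic orbits
("brake orbits") that continue the linear eigenmodes, and against which
excited motions are compared.

## The pendulum model

Both links have length $l = 0.5$ m with mass distributed along the link
(center of mass at $l/2$, central inertia $J_i = m_i l^2/12$; a single
link's total inertia about its joint is thus the familiar $m l^2/3$).
Rotational springs act in both joints, $K = \mathrm{diag}(k_1, k_2)$, and
the equations of motion are

$$M(q)\,\ddot q + C(q,\dot q)\,\dot q + K (q - q_\mathrm{eq}) + D \dot q = 0,$$

with the mass matrix depending on the relative angle $q_2$ only through
$\cos q_2$. The Coriolis matrix is not independent input: it is derived
from $M$ via Christoffel symbols, the unique construction making
$\dot M - 2C$ skew-symmetric (verified property-style over 1000 random
states). The drive enters as the moving equilibrium of the first spring:
the commanded motor-link angle $\theta$ replaces $q_{\mathrm{eq},1}$, so
the reflected torque is $\tau = k_1(\theta - q_1)$, an identity that holds
bit-exactly in every logged sample.

Default parameters follow the studied configurations: $m_1 = 0.5$,
$m_2 = 0.25$ kg, $k_1 = 5$, $k_2 = 3$ N m/rad, with presets `P0`, `P90`,
`P45` setting the second spring's equilibrium to 0, 90 or 45 degrees, and
variants with $m_2 = 0.625$ kg or altered $k_1$. The driven (experimental)
system adds viscous joint damping $d_i = 0.02\,k_i$ on the joint
velocities. We read "joint friction" as acting on the *relative* joint
velocities, which is the natural convention given that $q_2$ is defined
relative to link 1; for joint 1 the two readings coincide.

A deliberate modelling note: one often-quoted convention attaches
$J_i = m_i l^2/3$ inside the mass matrix. That double-counts the
point-mass terms already present in its off-diagonal structure — the
printed matrix's own single-pendulum reduction $M_{11} = J_1 + m_1 l^2/4$
equals $m_1 l^2/3$ only with the central inertia $m_1 l^2/12$. The central
convention also reproduces the reference periods (1.29 s / 1.08 s at
2.5 J) to three digits, so it is used throughout.

## Simulation of the 1 kHz closed loop

The experimental loop commanded and logged at 1 kHz. `simulate()`
reproduces this: the controller is queried once per sample with
`(t, state, previous command)`, the command is held (zero-order hold), and
the continuous dynamics are advanced between samples by classical RK4 with
4 substeps (0.25 ms). We chose a fixed-step scheme over an adaptive one
for bit-reproducibility and a simple compiled inner loop; its accuracy is
certified rather than assumed: an undriven conservative 40 s run on a 2.5 J
brake orbit drifts by less than $10^{-9}$ J against a $10^{-6}$ J
requirement. Brake-orbit computation, where orbit-level accuracy matters
most, instead uses an adaptive multistep integrator (`deSolve::lsodar`,
`rtol = 1e-12`) with continuous event location.

## Brake-orbit shooting and continuation

At energy $E$ the candidate turning point lives on the potential level set
$\tfrac12 (q-q_\mathrm{eq})^\top K (q-q_\mathrm{eq}) = E$, an ellipse
parametrized by one angle $\psi$ — the energy constraint removes one of
the two unknowns. Shooting integrates from rest at $q(\psi)$ until the
first joint velocity crosses zero and takes the second joint velocity
there as the scalar residual; at a true turning point both vanish
together. Two numerical details matter:

* **Event arming.** Near a turning point $\dot q_1$ hovers around zero, so
  the "first zero crossing" is ambiguous immediately after departure. The
  event is armed only once the kinetic energy first exceeds $E/4$ — a
  braking swing must pass the high-speed region — which removes spurious
  early events that otherwise stall the continuation of the `P45` family
  at intermediate energies.
* **Root solve.** A damped Newton iteration on $\psi$ (numeric derivative,
  step capped at 0.3, halving on non-improvement) drives the residual
  below $10^{-9}$ rad/s.

Continuation starts from the linearized mode at $E = 10^{-3}$ J (where the
orbit period matches $2\pi/\omega_1$ to 0.1%) and raises the energy in
steps of 0.05 J with a linear predictor for $\psi$, halving the step on
failure down to $10^{-3}$ J before giving up with a partial family. Orbits
at intermediate energies are always re-solved (seeded by interpolating
$\psi$), never interpolated. Each orbit stores its path at 1000 samples
per period. Mode 1 is the default throughout the task pipeline (it is the
more stable of the two); mode 2 is computed on request.

## Targets and scoring

Targets are disks of radius 0.1 m (0.05 m in the increased-accuracy
variant) centered on the forward-kinematic tip positions of the brake
orbit's turning points at the task energy, 2.5 J. For the deliberately
off-mode `P45` task the centers are instead placed between the
corresponding-side `P0` and `P90` targets at their polar midpoint about
the pendulum base; the exact placement is a declared convention (the
original arrangement is given only pictorially), kept in one place so
alternatives can be tested. For the heavier-mass variants the targets stay
at the original positions, whose turning points they still cover at the
reduced task energy 2.3 J.

Scoring follows the task's state machine: hit detection re-arms at every
sign change of $q_1$ (the tip-bearing link crossing the first joint's
equilibrium axis), forcing alternation. The swing's turning point is the
sample of minimal Cartesian tip speed between two crossings. Inside the
closed disk it is a hit; otherwise the tip's polar angle against the
target center's angle, taken along the swing direction, separates
undershoots from overshoots. This angular operationalization replaces the
original mesh-collision test; it agrees with it for swings that approach
the targets along the arc, which is how these pendula move.

Because our damped model dissipates slightly less than the original
real-time implementation, the empirically tuned open-loop amplitudes
(BL1's 0.12 rad, BL2's 1.0 rad) settle marginally beyond the target disks
here: the baselines reach the targets but register overshoots where the
original registered hits. All cross-strategy comparisons are unaffected;
absolute hit totals were never desk-reproducible (their counting
convention is unresolved) and are excluded from acceptance checks.

## Baseline controllers

* **BL1** — sine at the mode's eigenfrequency $1/T(E)$, amplitude 0.12
  rad: the resonance hypothesis.
* **BL2** — sine at half that frequency, amplitude 1.0 rad: quasi-static
  position control that avoids spring deflection.
* **BL3** — bang-bang with deadzone: each sample computes
  $\tau = k_1(\theta_\mathrm{prev} - q_1)$ from the *previous* command
  (the 1 kHz zero-order hold resolves the otherwise circular
  self-reference) and jumps to $+0.5$, $-0.5$ or 0 rad on the threshold
  $\epsilon_\tau = 1$ N m. From rest the deadzone is absorbing, so the
  first sample is forced to $+\hat\theta$; steady behavior is independent
  of the kick sign (tested with both).

## Metrics

* **Oscillation frequency** — reciprocal of twice the mean interval
  between turning points.
* **Mode metric $\eta$** — dynamic time warping between the averaged
  excited cycle and the brake orbit, both resampled to $N$ points and
  aligned at the same-side turning point, over the four dimensions
  $(q_1, q_2, \dot q_1, \dot q_2)$. The cost per aligned pair is the
  squared difference summed over dimensions — no square root, following
  the metric's defining sum — and the warping is boundary-anchored,
  monotone, unit-step. $\eta$ grows with $N$ and mixes rad with rad/s
  unweighted; both caveats are inherent to the definition, so $N$ is fixed
  at 1000, reported with every value, and only comparisons at shared $N$
  are meaningful. The dynamic program is verified against exhaustive
  enumeration of all admissible warpings for short series.
* **Cycle averaging** — only periods whose two turning points were both
  hits enter the average (energy was maintained). For deterministic
  baselines whose steady cycle misses the disks this filter would exclude
  everything, so it falls back to all periods; participants' logs
  virtually always contain qualifying periods.
* **Deflection ratio $\rho$** — per-period $\max|\theta| / \max|q_1|$,
  averaged.
* **Phase lag $\phi$** — cross-correlation lag between mean-removed
  $\theta$ and $q_1$, reported as the lag of the pendulum behind the motor
  command (the drive leads the response) and scaled by $2\pi/T$; a planted
  lag on noiseless sinusoids is recovered to within one sample.
* **Path-length ratio** — total variation of $\theta$ over that of $q_1$,
  as a percentage.
* Handle-motion descriptors discard the first 5 s of each trial as
  transient; trials are prepared by dropping the worst of four by hit
  count (earliest on ties), cutting each survivor from its first turning
  point to its last opposite-side turning point, and concatenating.

## The synthetic cohort

The generator is explicitly a stand-in for human joystick behavior, not a
claim about human control. Its mechanism is the minimal one reproducing
the observed signatures: a phase-tracking oscillator estimates the
pendulum phase from $(q_1, \dot q_1)$ and commands
$\theta = \mathrm{shift} + A_t \cos(\mathrm{phase} + \phi_\mathrm{lag}) +
\mathrm{noise}$, with $A_t$ adapted at every turning point toward the
targets (increase on undershoot, decrease on overshoot, dead-banded at the
target radius). Per-participant parameters are drawn once and held across
trials: $\phi_\mathrm{lag} \sim U(0.15\pi, 0.70\pi)$ (the observed range),
$\mathrm{shift} \sim N(0, 0.05)$ rad, motor noise
$\sigma \sim U(0.005, 0.02)$ rad, a coin-flip "plateau" habit that holds
the command for 50 ms after each equilibrium crossing (the plateau length
is a placeholder for a qualitatively described feature), and a fixed
adaptation gain of 0.6 rad/m. Each trial simulates 5 s of settle-in before
the recorded 40 s, mimicking recordings that start once a rhythm is found;
each configuration's first trial carries inflated noise so the worst-trial
exclusion is exercised deterministically.

Two honest limitations. First, a phase-locked drive away from quadrature
detunes the closed loop: steady oscillation sits within 1% of the
eigenfrequency at mid-range lags but up to ~7% below it at the lower end
of the lag range (0.93 of the eigenfrequency at $0.2\pi$), the same
direction of shift seen in the human cohorts.
Second, the model has no learning, no biomechanics and no visual-cue
effects, so passing tests demonstrate that the *pipeline* recovers planted
behavior (phase lags correlate with the planted values at $r > 0.95$
across a cohort), not that humans behave this way.

## Statistics

Baselines are deterministic, so only per-participant differences to each
baseline are testable: two-sided one-sample t-tests at the
Bonferroni-corrected level $0.05/3$, normality screened by a KS check on
the standardized sample (conservative by construction), Pearson
correlations for phase-lag/performance relations, and a one-way ANOVA
with Tukey post-hocs to verify the baselines differ among themselves. All
tests delegate to R's standard implementations; their type-I behavior is
calibrated by Monte Carlo in the test suite.

## Problem sizes

The test suite runs continuations to 2.5–3 J (step 0.05 J for
acceptance-grade families, 0.25 J for shared fixtures), 40 s closed-loop
trials at 1 kHz, a 20-subject single-configuration cohort for the
recovery check, and $10^4$-replicate calibrations; the full suite
completes in about ten minutes on one core. The `analysis/` scripts run
the complete study layout (20 subjects, three experiments) in roughly the
same time.
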