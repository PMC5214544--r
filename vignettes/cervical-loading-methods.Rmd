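---
title: "Methods: whole-body musculoskeletal simulation of cervical spine loading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-body musculoskeletal simulation of cervical spine loading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervidyn)
```

## The model

cervidyn simulates a full-body rigid-body tree built from a hierarchical
text description: segments carry mass, a local centre of mass and principal
moments of inertia; joints connect segments through ordered single-axis
rotational or translational coordinates; coordinate-coupler constraints
express one coordinate as a spline or affine function of another. Internally
every coordinate becomes one node of an expanded single-axis chain, so a
ball joint is three stacked revolute nodes with massless intermediates.
Forward kinematics composes the node transforms root to leaf; inverse
dynamics is a recursive Newton-Euler pass in the ground frame (compiled,
with a plain-R reference implementation kept as a cross-check in the test
suite); the mass matrix is assembled column-wise from unit-acceleration
inverse-dynamics calls with gravity off.

Coupler-driven coordinates are eliminated rather than enforced by Lagrange
multipliers: with `q = gamma(q_ind)` and velocity map `G`, the reduced
system is `G^T M G qddot_ind = G^T (Q - bias - M c)`, where `c` collects the
coupling-function curvature terms `f''(q_ind) qdot_ind^2`. Constraint
generalized forces are reconstructed on demand from the full-space residual
(dependent coordinate rows give the multipliers directly, chained couplers
are resolved in reverse dependency order). This is what makes the
workless-constraint audit sharp: the reconstructed forces are orthogonal to
every admissible velocity by construction, so any nonzero transmitted power
indicates an implementation defect, and the audit measures it at round-off
(~1e-16 W) rather than at an integration tolerance.

The packaged full-body description audits to 35 segments (counting the
ground root — a tree with n nodes has n − 1 edges, hence 34 joints), 73
coordinates, 30 couplers, 43 independent coordinates and 37 after the wrist
and metatarsophalangeal locks, 78 muscle-tendon units in 19 groups, and 23
coordinate torque actuators. The cervical chain has eight joints from the
neck base to the head: the three rotations of the lowest joint are the
*master* coordinates, six intermediate joints follow them through linear
couplers with level fractions from a data file
(`cervical_coupling.tsv`, a flagged default — the level-by-level
distribution is an assumption, overridable in the config), and the
uppermost joint is independent. The scapula-clavicular joint contributes
six couplers per side: three splines mapping humeral elevation (validated
span 20–140 degrees) to the sternoclavicular angles and three affine maps
from those to the acromioclavicular angles. Out-of-range elevations raise
an error at the API unless clamping is requested; silent extrapolation
would be untraceable.

## Muscles and strength scaling

Muscle-tendon units are Hill-type with a rigid tendon: fiber length follows
from path length minus tendon slack under a constant-thickness pennation
assumption. The curve constants live in one data file
(`hill_constants.tsv`) so the formulas are reproducible outside the
package: a Gaussian active force-length bell of width 0.45, an exponential
passive curve with shape factor 4 reaching one normalized force at 35%
strain, a Hill hyperbola for shortening with curvature 0.25, an eccentric
plateau at 1.4, and a maximum shortening velocity of 10 optimal fiber
lengths per second. The passive strain constant is deliberately at the stiff
end of the published range: the model has no ligament or disc elements, so
passive muscle is the only stabilizing tissue, and a softer curve leaves the
passive chain without a usable operating range (see "Passive behaviour"
below).

The packaged 78-unit muscle set is synthetic. Attachments are plausible
straight lines or two-segment paths chosen so that extensor lines run
nearly vertically (their lateral offsets match at origin and insertion) and
lateral-bending leverage is concentrated in the flexor/lateral groups.
Optimal fiber and slack lengths are set from the neutral-posture path
length in the proportion 0.65/0.35, with the optimal length shortened so
fibers carry about 8% stretch at neutral: this bilateral passive
pre-tension gives the unloaded chain positive stiffness (with fibers
exactly at optimum the passive chain has zero stiffness at neutral and
buckles under any perturbation). Baseline group strengths are calibrated
once, at generation time, so the maximal extension and lateral-bending
capacities equal the published baseline head-neck model's 34.1 and
22.6 N m; the published strength-scaling arithmetic then carries over
unchanged.

Two capacity-related definitions deserve care. First, because the cervical
masters drive six additional joints, the generalized force about a master
is roughly six times the physical moment at any one joint. Capacity is
therefore defined as the physical moment transmitted across the neck-base
joint — moment arms taken as plain partial derivatives at that joint, not
along the constrained manifold — which is what a dynamometer fixed at the
neck base measures. `moment_arm()` exposes both conventions
(`constrained =` TRUE/FALSE), and the tendon-excursion and effective-torque
routes agree to 1e-8 m under either. Second, strength scaling multiplies
only `F_max`; geometry is untouched, so moment arms are bit-identical
before and after scaling, and muscles whose primary action is lateral
bending or axial rotation carry the factor of their flexor/extensor class
(the published procedure scales only by that classification).

## Verification protocols

**Workless constraints.** A servo (PD gains 300 N m/rad, 60 N m s/rad,
minimum-jerk reference) drives humeral elevation from 25 to 135 degrees
over ten seconds with every other independent coordinate locked; the audit
reconstructs the coupler forces along the resulting motion and reports the
peak transmitted power plus, when external loads are present, the scalar
product of those loads with their application-point velocities.

**Passive loading.** A pure couple is applied to C2 about a body-frame
anatomical axis with all activations at zero, and the chain is
forward-integrated with viscous damping (default 0.5–2 N m s/rad; the
damping shifts no equilibrium of the conservative passive system) until
`max |u| < 1e-4 rad/s` over a 0.5 s window. Two protocol choices are ours:

* *Gravity compensation* (default on): a constant generalized torque
  balances gravity at the start posture, emulating a mounted in vitro
  specimen loaded by pure moments. Without it the passive chain sags and —
  since passive muscle tension is physiologically small — the head's weight
  exceeds the muscle-only stiffness, an instability the source models share
  in spirit (their lateral-bending and axial-rotation stiffness is also
  acknowledged as under-represented without discs and ligaments).
* *Planar loading*: for each movement only the in-plane master and head
  coordinates are unlocked (the applied couple's plane), reflecting the
  planar in vitro protocol and avoiding spurious out-of-plane buckling of
  the ligament-free chain.

**Isometric moments.** With the posture fixed, agonists (moment-arm sign
matching the requested direction, magnitude above 1e-6 m) are set to full
activation and antagonists to zero; the net moment is the moment-arm
weighted sum of tensions, so it scales exactly with the group factors
whenever antagonist passive force is zero.

## Inverse pipeline

Inverse kinematics solves the weighted least-squares marker fit per frame
by damped Gauss-Newton with analytic point Jacobians chained through the
coupler map, warm-started from the previous frame; frames with fewer than
three visible markers are flagged and cubic-interpolated up to a 0.2 s gap
limit. Inverse dynamics differentiates coordinates by central differences
(the 12 Hz third-order zero-phase Butterworth preprocessing is available as
`lowpass_filter()` and applied explicitly by the caller or the CLI).
Joint reactions follow the leaf-to-root force balance
`R_j = m_j a_j - (sum F_ext + sum F_const + R_(j+1))` with gravity among
the external forces; muscles contribute nothing unless activations are
supplied (then their path forces enter as external point forces), and the
reported reaction is the force the parent exerts on the child, in the
ground frame or rotated into the child frame.

Activation estimation replaces a tracking controller with per-frame static
optimization: at fixed kinematics and zero fiber velocity, muscle force is
affine in activation, so the moment balance with heavily penalized reserve
torques is a smooth box-constrained convex program solved by L-BFGS-B with
analytic gradients. Activation-rate limits between frames follow the
first-order activation dynamics (time constants 10/40 ms by default). Both
published objectives are exposed — the sum of squared activations and the
sum of muscle forces — and neither is asserted as canonical, since the
source material itself uses both descriptions.

The EMG chain is band-pass (10–500 Hz, Butterworth order 2, zero-phase),
full-wave rectification, a 50 ms moving rectangular window, and division by
an MVC reference. The band-pass precedes rectification: rectifying first
and then band-passing above 10 Hz would remove the envelope's own
low-frequency content, so the comma-ordering of the published description
cannot be the literal signal path; the set of operations is identical.
Zero-phase filtering pads the series with reflected ends long enough
(8 time constants of the lowest corner) for the filter transient to decay,
because `signal::filtfilt` starts from zero state.

## Synthetic data

The generators emulate the published acquisition set-up at desk scale:
68-marker trajectories from smooth C2 coordinate bumps plus seeded
isotropic Gaussian noise (markers at 20–100 Hz in the tests), shoulder and
foot force profiles with a pre-engagement bump, an 80 ms engagement ramp, a
transient decay and a sustained push at 60% of peak (a stylization of the
phase structure, not a fit to measured spectra; foot loads carry body
weight exactly at standstill), and EMG-like signals as 20–450 Hz
band-limited noise amplitude-modulated by a known activation trace at
2000 Hz. Every generator is deterministic under its seed and returns its
ground truth. What passing tests show is that the *pipelines* are correct —
round trips recover known coordinates, activations and envelopes; what they
cannot show is anatomical fidelity of the packaged geometry or realism of
soft-tissue artifact, which the generators do not model.

## Numerical choices and problem sizes

SI units throughout; degrees only at I/O boundaries. Default integrator:
`deSolve::lsoda` at rtol 1e-6 / atol 1e-8 (energy-conservation oracles use
1e-10/1e-12). Moment arms use a 1e-6 rad central difference. Gauss-Newton
stops on 1e-12 steps with Levenberg damping from 1e-6. The reserve penalty
weight is 1e4 (N m)^-2. Quasi-static detection thresholds are stated above.
The test suite runs the full-body model with short trials (around fifty IK
frames, four- to ten-second simulations, chains of up to seven links for
the oracles) — sizes chosen so the whole suite exercises every pipeline end
to end in about a minute while the oracle tolerances (1e-8 m arms, 1e-9 N
reactions, 1e-3 N m round trips, 1e-6 relative energy drift) stay sharp.

## Known limitations

* No wrapping surfaces, scapulothoracic gliding constraint, closed-loop
  shoulder chains, or elevation-plane dependence: the shoulder rhythm is
  valid for elevation in the scapular plane over 20–140 degrees only.
* No ligaments or intervertebral discs: passive stiffness is muscle-derived
  (plus optional per-coordinate bushings, off by default), hence the
  gravity-compensated, planar passive protocol.
* The published per-segment inertia table is consumed verbatim even though
  its cervical rows violate the rigid-body triangle inequality
  (`Iyy > Ixx + Izz`); the validity check applies to user-declared segment
  inertias at load time, not to the population tables.
* Bilateral mass fractions are interpreted per-side (they sum to ~100% of
  body mass only when paired segments are counted twice); the applied total
  is renormalized to the requested body mass by default.
* The packaged muscle set is not anatomically validated; flexion capacity
  in particular is not calibrated (only extension and lateral bending are),
  and population comparisons are structural properties (ordering,
  monotonicity), not physiological predictions.
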