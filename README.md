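# cervidyn

Whole-body rigid-body musculoskeletal simulation for the analysis of
cervical spine loading, written for biomechanists who study how the neck is
loaded during upper-limb and contact activities (sports collisions, ergonomic
and transport scenarios) where the external load enters through the shoulder
girdle and feet.

## What the package models

The core is a full-body rigid-body tree: 35 segments (counting the ground
root), 34 joints and 73 generalized coordinates, of which 30 are eliminated
by *coordinate-coupler constraints* — holonomic constraints of the form
`q_dep = f(q_ind)` — leaving 43 independent degrees of freedom (37 after the
wrist and metatarsophalangeal coordinates are locked). Two features carry the
scientific load:

* **A scapula-clavicular joint driven by humeral elevation.** The
  sternoclavicular joint's three rotations are spline functions of humeral
  elevation in the scapular plane, and the acromioclavicular rotations are
  linear functions of the sternoclavicular angles (six couplers per side).
  Because the couplers are workless — constraint forces are orthogonal to
  every admissible velocity — shoulder loads can be applied without the
  constraints injecting spurious energy, which the package verifies by
  reconstructing the constraint generalized forces
  `lambda` from the inverse-dynamics residual and reporting
  `P = (A^T lambda)^T qdot` along simulated motions.

* **Hill-type neck musculature with population strength scaling.** 78
  muscle-tendon units in 19 groups generate force
  `F = F_max (a f_l(l̃) f_v(ṽ) + f_p(l̃)) cos(alpha)` with a rigid tendon.
  Maximum isometric forces are scaled per flexor/extensor class by the ratio
  of in vivo neck strength to the baseline model's capacity, rounded to one
  decimal: 1.5 (extensors) and 1.4 (flexors) for a healthy male, 1.9 and 2.7
  for a front-row rugby player.

Around the core sit the standard pipelines: forward dynamics (reduced
equations of motion via recursive Newton-Euler, compiled in C++), passive
range-of-motion loading (2 N m flexion-extension / lateral bending, 4 N m
axial rotation applied at C2), maximal isometric moments with agonists fully
active and antagonists silent, marker-based inverse kinematics (damped
Gauss-Newton on 68 virtual markers), inverse dynamics, the leaf-to-root
joint-reaction recursion `R_j = m_j a_j - (sum F_ext + sum F_const +
R_(j+1))`, static-optimization activation estimation (sum of squared
activations or sum of forces), EMG envelope processing (band-pass 10–500 Hz,
rectify, 50 ms window, MVC normalization), and readers/writers for TRC,
STO/MOT and C3D motion files. Synthetic-data generators produce every input
with known ground truth.

The packaged muscle geometry is *synthetic*: attachments are plausible but
not anatomically validated, and the baseline maximal extension and
lateral-bending capacities are calibrated to the published head-neck model's
values (34.1 and 22.6 N m). All quantitative claims rest on mechanics, not
physiology; see the methods vignette.

## Worked example

```r
library(cervidyn)

am <- assemble(load_model_description(default_model_path()))
audit_degrees_of_freedom(am)
#> Model structural audit
#>   n_segments                 35
#>   n_joints                   34
#>   n_coordinates              73
#>   n_constraints              30
#>   n_independent              43
#>   n_independent_after_locks  37
#>   n_muscles                  78
#>   n_muscle_groups            19
#>   n_torque_actuators         23

## population-specific strength scaling and neck capacity
rugby <- apply_strength_scaling(am, strength_scaling("Rugby"))
neck_capacity(rugby, "extension")
#> <isometric moment about neck_flexion (dir -1)>: -64.09 N m (34 agonists, 36 antagonists)

## workless-constraint audit over a simulated humeral elevation sweep
sim <- simulate_humeral_elevation(am, duration = 10)
audit <- constraint_power_audit(attr(sim, "model"), sim)
attr(audit, "max_abs_total")
#> [1] 3.018425e-16
```

The audit says the scapula-clavicular couplers transmitted at most ~3e-16 W
during the ten-second sweep — zero to round-off, i.e. the constraints are
workless. The capacity is the net moment the fully activated extensors
produce across the neck-base joint against the silent flexors' passive
resistance: 34.1 N m unscaled, 64.1 N m after rugby scaling.

A thin command-line interface wraps the same functions:

```sh
inst/cli/cervidyn audit-constraints --duration 10
inst/cli/cervidyn isometric-moments --population rugby
inst/cli/cervidyn passive-rom --movement flexion_extension --moment 2
inst/cli/cervidyn ik --trc trial.trc
```

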