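---
title: "Probabilistic uncertainty analysis of a lower-limb musculoskeletal model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic uncertainty analysis of a lower-limb musculoskeletal model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the model, the simulation stack, the stochastic perturbation scheme, the
statistics, and the numerical and design choices a maintainer would want
spelled out.

## The model

The skeletal system is a 7-segment articulated linkage: pelvis, and thigh,
shank and foot per side. The pelvis connects to the ground through a
6-DOF free joint (three translations along the ground axes, then a Z–X–Y
sequence of rotations about the pelvis anatomical axes); each hip is a
3-DOF ball joint, each knee and ankle a 1-DOF hinge. The "10 degrees of
freedom" of the standard build counts only the articulated hip/knee/ankle
coordinates — a mobile root is required to track gait, so the free joint
is additional, as is conventional in movement-simulation software.

Body frames follow ISB-style recipes, built from the 21 standard
anatomical landmarks (x anterior, y cranial, z to the subject's right):

* **pelvis** — origin at mid-ASIS; z along the inter-ASIS line; x towards
  the front, orthogonalized against the mid-PSIS point;
* **thigh** — origin at the hip centre landmark; y from the mid-epicondyle
  point to the hip centre; z lateral via the epicondyle pair;
* **shank** — origin at the mid-condyle point; y from mid-malleolus to
  mid-condyle; z lateral via the condyle pair;
* **foot** — origin at the calcaneus; x towards the mid-metatarsal point;
  y normal to the plantar landmark plane.

The literature states only that frames follow the ISB convention; the
exact landmark subsets per segment are therefore a documented choice of
this package, fixed by the recipes above. Left-side frames use the
medial/lateral landmark pairs swapped so both sides share one axis
convention, which keeps hinge-angle signs comparable across legs.

Joint centres and axes are landmark-derived: the hip centre is itself a
landmark, the knee hinge is the trans-epicondylar line and the ankle hinge
the trans-malleolar line. Because frames, joints and inertia are all
recomputed from the landmark cloud, perturbing a landmark propagates to
every derived quantity.

Segment inertia assumes each body is composed of a bone and a soft-tissue
part with uniform densities of 1.42 and 1.03 g/cm³. Geometry uses
primitives (cylinders for the long segments, ellipsoids for the pelvis)
sized from landmark distances and the segment mass budget; meshes are out
of scope, consistent with segmentation uncertainty being excluded from
the perturbation scheme. The template assigns mass fractions 0.100
(thigh), 0.0465 (shank) and 0.0145 (foot) per side, with the remainder
lumped into the pelvis so that the model carries the full body mass —
necessary for the synthetic trials to be dynamically consistent with a
ground reaction equal to body weight.

Musculotendon units are polylines (origin, optional via/pseudo points,
insertion) fixed in their host bodies; no wrapping surfaces. Maximum
isometric force is `Fmax = (Vol / l_o_s) * sigma` with
`l_o_s = l_o_g * (L_mt_s / L_mt_g)`: the subject optimal fiber length is
assumed proportional to musculotendon length, the subject musculotendon
length `L_mt_s` is measured on the model at the neutral pose, and sigma
defaults to 61 N/cm². Units: SI throughout the core (m, kg, N, rad);
muscle architecture is entered in cm/cm³ and converted at this one
boundary.

## The simulation stack

**Inverse kinematics** minimizes the weighted sum of squared
marker-to-model-landmark distances per frame, by damped Gauss–Newton with
analytic geometric Jacobians, warm-started from the previous frame.
Default weights are 1; the upstream marker-processing choices of an
experimental protocol are outside the package, so no filtering is applied
by default.

**Differentiation** is central differences on the uniform time grid
(one-sided at the ends), with no smoothing by default — synthetic data
are noise-free, and the generator deliberately uses the *same* discrete
convention (below).

**Inverse dynamics** uses a Jacobian-transpose (d'Alembert) formulation
equivalent to recursive Newton–Euler over the tree, with velocities and
accelerations propagated analytically through the elementary joints. The
generalized force at every coordinate is returned: the articulated ones
are the net joint moments, and the six root coordinates form the residual
wrench, reported rather than discarded. The implementation is validated
against a closed-form Lagrangian double pendulum to 1e-8 relative.

**Static optimization** solves, per frame,

```
min  sum(a_i^2) + w_res * sum((Mres_j / M_scale)^2)
s.t. sum_i r_ij a_i Fmax_i + Mres_j = M_j,   0 <= a_i <= 1
```

with `w_res = 1e3` and `M_scale = 1` N·m. Reserve torques are eliminated
through the equality constraint, leaving a strictly convex box-constrained
QP solved exactly by a primal active-set method (KKT residual below
1e-6). Force–length–velocity muscle properties are deliberately not
modelled. Reserves are kept as penalized variables rather than excluded
because the failure filter is defined on their magnitude.

**Joint reaction analysis** computes the bone-on-bone force at each joint
as the free-body resultant of the distal subtree minus external loads and
minus the pull of every muscle crossing the joint, applied along the path
segment spanning it. Action–reaction antisymmetry is exact by
construction and verified in the tests.

**Moment arms** use the tendon-excursion definition, `r = -dL_mt/dq`,
computed analytically from the geometric Jacobian of the path points. The
method is a package choice (the definition is standard; the literature
rarely states the algorithm); an independent central-difference route
(`h = 1e-6` rad) is kept as a cross-check and agrees to below 1e-6 m.

## Stochastic input variables

Three categories, each with the constants housed in `run_config()`:

1. **Landmark positions** — 3 normal variables per landmark, zero-mean
   offsets along the body-frame axes with the packaged per-landmark SDs
   (`inst/extdata/landmark_sd.csv`, mm). Left-side landmarks mirror the
   right-side SDs, a documented default where the experimental table
   covers one side. Perturbations are applied to the landmark cloud
   *before* frame construction, so frames, joints, inertia and kinematics
   all inherit them.
2. **Musculotendon points** — origins and insertions are constrained to
   their attachment areas: a principal-axes fit of the area point cloud
   yields a plane (2 perturbation directions) or, if the first-to-second
   principal extent ratio reaches 3.0 (a configurable threshold the
   literature leaves unspecified), a line (1 direction). Pseudo-origins
   and pseudo-insertions move along all three host-body axes. All offsets
   are normal with SD 5 mm. Interior via points are not perturbed.
3. **Maximum muscle tension** — one variable, uniform on 35–137 N/cm²,
   entering every `Fmax` linearly; PCSA stays at its baseline value, so
   sampling sigma rescales all muscle strengths together.

The realized variable count is whatever the model yields (264 for the
default template: 111 + 152 + 1); the engine never assumes a fixed total,
because the count depends on the attachment-area geometry.

Sampling is Latin hypercube: one draw per equal-probability stratum per
variable, randomly paired across variables, reproducible under a single
master seed. Model instantiation is a pure function of the baseline
definition and one sample row.

## Monte-Carlo orchestration and statistics

Each trial runs IK → differentiation → ID → static optimization → joint
reaction; stage failures are captured, not raised. A trial is
*unsuccessful* when any reserve torque exceeds 5% of that DOF's peak net
moment in any stance frame — joint dynamic equilibrium required
non-negligible non-muscular torque — and unsuccessful trials are excluded
from analysis. More than 50% failures aborts with a configuration error.

Outputs are resampled linearly to a 101-point 0–100% stance grid; angles
in degrees, moments in N·m, muscle and contact forces in body weights.
Convergence is assessed post hoc on the frame-resolved outputs: over the
last 10% of simulations, running means and SDs must stay within 2% of
their final values; outputs whose final value is below 1e-6 in native
units switch to an absolute tolerance, because a relative rule is
meaningless at zero. Both the per-frame default and the rule itself are
configurable.

Band statistics use the unbiased (n−1) SD. The correlation analysis
computes, for every (output, input, stance-%) cell across successful
trials, the R² of the simple linear regression (identical to the squared
Pearson correlation, asserted to 1e-12 in tests) with the two-sided
correlation t-test on n−2 degrees of freedom. Significance uses raw
p < 0.001 with no multiple-testing correction, matching standard practice
for this analysis; reporting thresholds are R² 0.2 and 0.7, and the
contact forces are the designated outputs. Because the denominator behind
"percent significant" can be counted per cell or per input variable, the
summary reports both conventions, labelled.

## The synthetic-data generator

The generator stands in for a subject's imaging and gait data. The
template anatomy (1.83 m, 70.5 kg by default) places the 21 landmarks at
anthropometry-scaled coordinates, mirrors the left side, and defines 16
musculotendon units per leg — the major hip abductors/flexors/extensors,
the quadriceps, the triceps surae and tibialis anterior — with volumes
and generic lengths from a packaged, editable table of plausible
magnitudes. Attachment areas are symmetric point clouds centred exactly
on each origin/insertion (so the zero perturbation is the identity), with
a few deliberately elongated areas to exercise the line-mode fit.
Template coordinates are versioned plumbing: they claim topological and
dimensional plausibility, not any subject's anatomy.

The stance trial prescribes smooth joint-angle programs over a 0.6 s
stance sampled at 50 Hz (31 frames — desk-scale sizes chosen so the full
Monte-Carlo remains interactive; the grid is a parameter). The pelvis
trajectory is *derived* so the right foot stays exactly planted at its
calibration pose; with a flat-planted foot, forward progression appears
as monotonically increasing ankle dorsiflexion, and the progression rate
is mildly decelerating so the centre of pressure sweeps monotonically
heel to toe. Ground reactions are computed from whole-body Newton–Euler
balance — using the same finite-difference derivatives as the analysis
pipeline, so the discrete system is *exactly* consistent and the root
residual is zero to machine precision at zero marker noise. The centre of
pressure comes from the moment balance, clamped into the footprint, with
the residual absorbed by the plate torque vector (the vertical component
is the usual free moment; tiny horizontal components can appear at the
clamp and are recorded, not hidden). Ground truth (coordinates, moments,
residuals) is stored with the trial for recovery tests.

What passing tests on these data do and do not show: they validate the
solvers, the propagation machinery and the statistics exactly, because
every oracle is closed-form or independently coded; they do not establish
anything about soft-tissue artifact, marker noise structure, real muscle
geometry, or any specific subject — the generator has no such features,
and empirical SD magnitudes on the template transfer to real models only
in order of magnitude.

## Numerical choices and degenerate inputs

* Gauss–Newton IK: Levenberg damping 1e-6 (1e-3 fallback on a singular
  normal matrix), step tolerance 1e-10, 60 iterations; non-convergence
  flags the frame and warns.
* Box QP: primal active set, clamp-worst-violator inner loop, single
  release per outer cycle, 200 cycle cap; KKT tolerance 1e-10 for
  release, residual reported.
* Attachment fit: eigen-decomposition of the scatter matrix; coincident
  points raise a named error; the 3.0 length/width threshold is logged in
  the variable ids (`plane1/plane2` vs `line1`).
* Zero-SD variables (one landmark coordinate has experimental SD 0.0) are
  degenerate normals: every sample equals the mean.
* A via point coincident with its neighbour contributes a zero-length
  segment and no excursion; within-body path segments are skipped in the
  moment-arm accumulation.
* Ensembles are stored as a directory of CSV/JSON files — a transparent
  hierarchical store whose round-trip is tested to reproduce band and
  correlation statistics exactly.

## Problem sizes

Defaults used throughout the examples, tests and the acceptance script:
31-frame stance trials, 32 MTUs, 264 stochastic variables, Monte-Carlo
ensembles of 100 samples (the convergence rule is also exercised against
its own brute-force re-implementation at N = 500 on scalar sequences).
These are the package's desk-scale study conditions; all of them are
parameters, and a 500-sample study is a single argument change.

## Known limitations

* Line-segment muscle paths without wrapping surfaces: moment arms of
  muscles that physically wrap (e.g. quadriceps over the femur at deep
  flexion) are only as good as the via-point placement.
* No activation dynamics, no force–length–velocity properties, no
  tendon-slack-length or fiber-length perturbations — all deliberately
  out of scope.
* The hinge knee/ankle and landmark-derived axes inherit landmark
  uncertainty but cannot express axis translation or six-DOF joint
  behaviour.
* The convergence rule compares running statistics to the *final* value,
  so it certifies stability of the estimate, not closeness to the
  infinite-sample limit.
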