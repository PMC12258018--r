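---
title: "Methods: bioimpedance simulation and thrombus detection in an ECMO oxygenator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bioimpedance simulation and thrombus detection in an ECMO oxygenator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical model and its assumptions

`oxeit` models the blood-filled interior of a hollow-fiber oxygenator as a
9 × 9 × 5 cm box at a single measurement frequency, so each material is a
purely real conductivity: blood 0.662 S/m, clot 0.0662 S/m (one tenth of
blood, the optimistic end of reported blood/thrombus contrasts),
polycarbonate separation grid 1e-6 S/m. The fiber bundle itself is not
modelled; its electrical effect is folded into the homogeneous background.
The separation grid — a lattice stiffening the bundle at mid-height — is
represented by two orthogonal sets of cylindrical rods (default 5 + 5 rods,
0.4 cm diameter, 1.8 cm pitch; the true manufacturer layout is not public,
so the lattice is configurable).

Electrodes may only contact blood at the top and bottom planes, on eight
radial spokes per plane (45° apart); an array is therefore described by 16
radial distances. This respects the housing geometry, keeps the
parametrization low-dimensional, and reaches the corners where stagnating
flow makes thrombus deposition most likely.

The forward problem is solved with linear (P1) tetrahedral finite elements
under the complete electrode model (CEM): finite circular contact patches
(default radius 0.004 m) with contact impedance (default 1e-4 Ω·m²).
Measured quantities are four-point voltages — current through one electrode
pair, voltage across a disjoint pair — which suppress the contact-impedance
contribution; results are reported as relative voltage differences
ΔV~r~ = (v − v~hom~)/v~hom~ against a clean homogeneous reference frame, so
they are invariant to the injection amplitude (nominally 1 A) and only
weakly sensitive to the nominal contact impedance.

## Meshing

The mesher is deterministic and structured: the box is divided into a
regular hexahedral grid no coarser than `max_h` per axis (default 0.002 m)
and each cell is split into six tetrahedra by the Kuhn subdivision. Two
consequences matter:

* Summed element volume equals the box volume exactly, at every resolution
  (the separation grid is an interior *label*, not a cavity).
* The six tetrahedra per cell realize all axis permutations, so the mesh is
  exactly invariant under the x ↔ y transposition — but **not** under 90°
  rotation, because the subdivision has a preferred cell diagonal. Symmetry
  checks in the test suite therefore use the diagonal mirror, which the
  discrete model honors to machine precision.

Elements are labelled `SG` when their centroid lies within a rod radius of
a grid-rod axis, `BG` otherwise. At `max_h` = 0.005 m the default geometry
yields 19,440 elements / 3,971 nodes; at 0.002 m it is in the 3 × 10^5
element range.

A related resolution effect: tetrahedron centroids of a cell sit at
per-axis offsets that are permutations of (3/4, 1/2, 1/4) of the cell size,
so the centroid cloud has a covering radius of about 0.56 `max_h`. A
spherical target must have a radius above this to be guaranteed to capture
an element; `insert_spherical_target()` raises an explicit error otherwise,
and the tiny (1 cm mesh) fixture uses 1.6 cm targets for that reason. On
coarse meshes an electrode patch may likewise contain no triangle centroid;
the solver then takes **all** triangles tied at the minimal distance rather
than an arbitrary single one, which keeps mirror-symmetric configurations
exactly symmetric.

## Gauge, factorization and the adjoint Jacobian

The CEM system (nodal potentials plus 16 electrode potentials) is singular
up to an additive constant; the gauge is fixed by grounding one mesh node.
All reported voltages are electrode-pair differences and independent of
this choice. Per conductivity field the sparse symmetric system is
factorized once (CHOLMOD Cholesky, symbolic analysis reused across fields)
and shared by all injection pairs.

Sensitivities use the adjoint identity
J[i,j] = −vol~j~ · ∇u~inj~ · ∇u~meas~ on element j, where u~meas~ solves
the same system with unit current through the measure pair. Because this is
the exact derivative of the discrete system, agreement with central finite
differences is limited only by solver round-off and the difference step;
the acceptance suite verifies max relative row error below 1e-3 on a
sub-2,000-element mesh.

## Measurement pattern selection

Candidates pair all intra-plane electrode pairs with inter-plane pairs
between spoke-aligned and spoke-adjacent electrodes (an `all-pairs` mode
exists); reciprocity duplicates — inject and measure pairs swapped — are
removed at enumeration since they carry the same transfer impedance. The
published enumeration ("sensible pairs", 1,560 candidates) is not exactly
recoverable; the default ruleset reproduces its intra/inter-plane structure
and its scale (2,440 candidates on the default array) and the count is
deliberately treated as scale guidance only.

Selection fills a 144/32/32 budget:

1. **Greedy Gram-volume maximization** (144 rows). Exhaustive subset search
   over thousands of candidates is combinatorially impossible; each greedy
   step adds the candidate with the largest orthogonal residual against the
   span of the selected rows, which is exactly the candidate maximizing the
   updated determinant. Ties break on the lowest candidate index. On
   exhaustively enumerable instances (12 choose 4) the greedy volume ranks
   in the top decile of all subsets.
2. **Top-32 by L1 norm**, then **top-32 by L2 norm**, skipping rows already
   selected, so the final pattern has exactly 208 distinct measurements.

One screen precedes selection: candidates whose homogeneous reference
voltage is below 1e-9 V (at unit current) are excluded. Relative voltage
monitoring divides by the reference, and measurements that are null by
symmetry are unusable in deployment however sensitive their Jacobian row
is; without this screen a selected frame can contain an exactly-zero
reference. The Gram criterion is evaluated as det(J J^T) itself — the
squared parallelotope volume — since ranking is unchanged by the square
root; the L1 norm uses absolute values, as a norm must.

## Thrombus placement sampling

The likelihood field is the exact reciprocal of an independent trivariate
normal density with μ = 0 and σ = (0.045, 0.045, 0.025) m — half the box
dimensions, read in meters for dimensional consistency — including the 1/2
factor in the exponent, so the central likelihood is
σ~x~σ~y~σ~z~(2π)^{3/2} ≈ 7.97e-4 and the corner/centre ratio is exactly
e^{3/2}. This is an empirical stand-in for the flow field (fast core,
stagnant rim), not a CFD result.

Placement percentiles are taken over the voxel-value CDF (fraction of
voxels with lower likelihood; voxel default 0.002 m). Since isolines are
ellipsoidal, many voxels share a percentile value; a draw picks uniformly
among voxels within a 0.5% relative band of that value (band widened once
by 10× before erroring). Training scenarios use 12 sets of 6 targets on a
shared percentile schedule, equidistant 5–98. Their diameter is not fixed
by the published protocol; the default is 0.01 m, matching the detection
grid. The detection grid itself is a regular lattice of 1 cm spheres fully
inside the box at a 4/4/5 mm pitch, giving 3,969 targets — the published
scale is 3,971, and the exact lattice is unstated, so the count is treated
as order-of-magnitude guidance.

## Neural components

Both networks are small fully-connected perceptrons implemented in base R
(no GPU framework is needed at these sizes), trained by mini-batch SGD with
classical momentum 0.9, initial learning rate 1e-3 decayed ×0.95 every 10
epochs, L2 regularization 1e-6, 200 epochs, on seeded 80/10/10 splits.
Momentum and the decay schedule are not fixed by the published protocol;
these defaults are conventional and config-exposed. Inputs are z-scored
with training-set statistics stored on the model (the published "scaled
input features" are ratios with ideal value 1; z-scoring is an affine map
and leaves the ideal-feature forward pass well defined). Validation loss is
monitored every epoch and best-validation weights are restored.

* **Surrogate** (3 → 254 → 203 → 48, leaky ReLU 0.01, regression):
  features are the three homogeneity ratios — median/min of J row L1 norms,
  max/min singular value of J, median/min of pooled |ΔV~r~| across the 12
  target sets. Which norm enters the first and third ratio is not pinned
  down by the published description; row L1 norms and raw |ΔV~r~| entries
  are used and recorded. The layer widths follow the published architecture
  table (the closed-form width formulas as printed are inconsistent with
  that table and are not used). Proposals come from a forward pass on
  [1, 1, 1], snapped to the nearest valid slots (collisions resolved by
  sending the farther electrode to its next-nearest free slot); an optional
  deterministic symmetrization sets each plane's spokes to their mean
  radial distance — an explicit operator, never applied silently, standing
  in for the published manual adjustment step.
* **Detector** (208 → 200 → 100 → 2, ReLU, softmax): classifies ΔV~r~
  frames; the predicted class is the softmax argmax.

Array uniqueness for the surrogate dataset follows the at-least-2-electrodes
-differ rule. With continuous radial draws exact duplicates are essentially
impossible, so at desk scale nearly every draw is unique; the rule is
enforced with a small positional tolerance and unit-tested on constructed
duplicates.

## Noise model of the detection dataset

Positives insert one spherical clot whose conductivity is drawn from
N(0.0662, (0.0662/10)²) S/m, truncated at 1e-4 S/m. Negatives perturb every
background element by N(0, (0.662/100)²) S/m. Both frames then receive
additive white Gaussian noise scaled to a fixed **power SNR on the ΔV~r~
frame** (default 15 dB, signal power ≈ 31.6 × noise power); the published
description does not fix whether the SNR is defined on raw voltages or on
ΔV~r~, and the frame-wise reading is adopted as the conventional one. A
zero frame stays zero. The same clean homogeneous reference serves every
sample, mirroring deployment, where the first frame after priming is the
reference. The split is stratified by class so that every partition
contains both classes even at smoke-test sizes.

What the generator does *not* emulate: hematocrit, flow and temperature
dependence of blood conductivity; clot-composition variability beyond a
single conductivity jitter; electrode drift or contact degradation;
correlated instrumentation noise; multiple simultaneous clots; realistic
clot morphology. Passing tests therefore demonstrate internal consistency
of the simulation-and-detection chain under these idealized conditions, not
clinical performance.

## Problem sizes used in the tests and the acceptance script

The package's own studies run at two deliberate scales: a `tiny` fixture
(1 cm mesh, 2,430 elements, 8-measurement pattern, 20-sample dataset) for
smoke and property tests, and a `small` study (5 mm mesh, 19,440 elements,
the full 208-measurement budget, 800 + 800 samples) as the quantitative
evaluation surface. The published full-scale configuration (2 mm mesh,
373k elements, 3,971 + 3,971 simulations) is supported by the same code
paths but is not what the bundled tests run; coarser meshes smooth the
sensitivity field, so detection metrics from the small study should be read
as the desk-scale operating point, with any shortfall first examined
against mesh resolution.

## Numerical choices and degenerate inputs

* Reference-voltage floor for ΔV~r~: 1e-12 V; below it the measurement is
  degenerate and an error names the offending rows.
* Rejection sampling of electrode radii preserves the truncated-normal
  shape (clipping would pile mass at the bounds); draws are capped at 10^4
  attempts before an explicit error (an infeasible mean, e.g. far outside
  the plane, is caught rather than looping).
* μ~elpos~ = 0.030 m, σ~elpos~ = 0.012 m defaults cover the full radial
  range with non-negligible corner probability; both unstated in the
  published protocol and config-exposed.
* Greedy-volume residuals are clamped at zero against cancellation;
  rank-deficient subsets yield Gram volume 0, never negative.
* Negative drawn conductivities are redrawn above 1e-4 S/m.
* Mesh elements are orientation-fixed to positive volume; a degenerate
  geometry aborts with the geometry echoed.

## Known limitations

Single-frequency real-valued conductivity only; no inverse reconstruction
(detection is classification, not imaging); no localization or sizing; the
flow-informed placement field is a Gaussian surrogate, not CFD; the mesh is
structured rather than boundary-fitted to the true housing; and all results
are simulation-only — experimental validation on a perfused mock loop is
the natural next step and outside this package's scope.
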