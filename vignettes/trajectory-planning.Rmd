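---
title: "CT-value-based pedicle screw trajectory planning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CT-value-based pedicle screw trajectory planning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pedicle screw fixation fails more often in osteoporotic bone: pull-out
strength tracks the bone mineral density (BMD) of the tissue the screw
thread engages, and BMD in turn is linearly related to the CT attenuation
value in Hounsfield units (HU). A surgeon planning a screw on CT therefore
has an optimization problem: among all corridors that respect the
anatomy, prefer the one passing through the densest bone.

`pediplan` implements that planner. Given a CT volume, a compartment
label volume (cortical shell, cancellous body, pedicles, spinal canal,
narrowest-pedicle-section ROI) and a screw size, it searches for the
trajectory maximizing the **mean HU of the cylindrical screw corridor**

$$\max_{e,\,u}\;\; \overline{\mathrm{HU}}\big(C(e, u; L, D)\big)
\quad\text{s.t.}\quad C \subset \text{bone},\;\;
C \cap \mathrm{ROI}_\text{pedicle} \ne \emptyset,\;\;
\text{tip clear of the anterior cortex},$$

where $C(e,u;L,D)$ is the cylinder of length $L$ and diameter $D$ with
entry point $e$ and unit direction $u$. The conventional manual plan —
through the midpoint of the narrowest pedicle section, parallel to the
endplate, on the pedicle axis — is provided as the baseline, and a
synthetic vertebra phantom with a decalcification model supplies ground
truth for validation.

## Corridor scoring

The corridor mean is a quadrature over a deterministic cylinder lattice:
axial stations every `step_axial` (default half the smallest voxel
spacing, midpoint rule), each station carrying the centerline point plus
concentric rings (default `rings = 3`; ring $j$ has $6(j-1)$ points at
the equal-area radius of its annular zone), all with equal weights. For
any affine HU field the lattice mean equals the field value at the
cylinder centroid exactly, and on the phantom the default lattice agrees
with an 8x-denser quadrature to well under 0.5%. HU values are read by
trilinear interpolation; sampling outside the scanned grid is an error
rather than padding, because a corridor leaving the scan is meaningless.

A centerline-only mean (`centerline = TRUE`) is available for
comparison; the volume-weighted mean is the default because screw
purchase depends on the bone occupied by the whole thread, not its axis.

## Constraints

Containment is decided against a Euclidean distance map of the bone mask
(anisotropy-aware exact EDT; distances are voxel-center to
voxel-center, with the region beyond the array edge counting as
exterior). The centerline is sampled at half-voxel steps and the screw
is contained where the interpolated distance to the bone exterior stays
at or above `diameter/2 + safety_margin` — boundary equality counts as
contained, and the default safety margin is 0 mm, since the objective
explicitly rewards corridors hugging the cortex.

One convention needs care: a real entry point lies *on* the posterior
bone surface, where the distance to the exterior is zero, so requiring
the full-radius clearance over the entire centerline would reject every
trajectory. Containment is therefore enforced from the first centerline
station at which the corridor is fully inside bone ("entry transition")
through the tip; a corridor that never achieves full clearance is not
contained, and one that exits and re-enters bone after the transition
fails too. For corridors that start deep inside bone the rule reduces
to the plain minimum-over-centerline criterion, which is what the
brute-force voxel-classification oracle in the test suite checks.

Passage through the narrowest pedicle section is required as a hard
constraint: the corridor lattice must touch at least one voxel of the
side's ROI label. The anterior margin check requires the tip to lie
inside the vertebral body (cortical or cancellous label) with at least a
corridor radius of clearance to the bone exterior. The screw is allowed
inside the cortical label itself — cortex is bone; only leaving the bone
mask is a breach.

The narrowest-section ROI labels necessarily *replace* pedicle voxel
codes in an integer label volume, so the bone mask is defined as
{cortical, cancellous, left/right pedicle, left/right ROI}.

## Measurement conventions

Positions are measured on the axial and sagittal views of a vertebral
frame (midline plane, lower endplate plane, craniocaudal axis):

* `d` — unsigned distance from the entry point to the midline plane;
  `theta` — axial-view angle between the screw axis and the
  perpendicular from the entry point toward the midline. The
  **abduction angle** is `90 - theta` (positive when the screw converges
  medially).
* `d'` — unsigned distance from the entry point to the lower endplate
  plane; `theta'` — sagittal-view angle between the screw axis and the
  endplate perpendicular taken on the entry side. The **craniocaudal
  inclination** is `theta' - 90` (positive caudal, negative cephalic),
  so a sagittal angle of 109.19 degrees is a 19.19-degree caudal tilt.

`reconstruct_trajectory()` inverts the two angles (for a given entry
point and anterior-pointing screw), and measure-reconstruct-measure is a
fixed point to 1e-6. Degenerate projections (screw axis parallel to a
view normal) raise errors instead of returning NaN so that optimization
loops fail loudly. The guideline is placed on the *lower* endplate,
matching the measurement-protocol figure of the study this design
follows; descriptions of screws "parallel to the upper endplate" differ
only by which endplate anchors `d'` and leave the angles unchanged for
parallel endplates.

Placement error between a planned and an actual (postoperative)
trajectory is the signed pair `(d1 - d, theta1 - theta)`.

## The automatic search

The optimizer is a deterministic two-stage derivative-free search; the
reference software this reimplements discloses only the objective and
constraints, so the scheme was chosen for reproducibility and
testability over stochastic metaheuristics:

1. **Grid stage.** Entry candidates are generated by sliding the
   pedicle axis over a square grid of in-plane offsets (step
   `entry_grid_step`, default 1 mm) within the narrowest-section
   half-width, and tracing each offset line back to the posterior bone
   surface. Directions sample a cone about the pedicle principal axis
   (half-angle 20 degrees, step 2 degrees by default) via a tangent-plane
   parametrization. Every candidate is feasibility-checked and scored;
   exact ties are broken lexicographically by (entry index, direction
   index), so flat objectives still yield bit-reproducible plans. The
   default cone comfortably covers the few-degree axial and
   15-20-degree sagittal deviations observed between automatic and
   manual plans.
2. **Pattern search.** From the best grid candidate, compass moves over
   the four degrees of freedom (two entry offsets in mm, two direction
   angles in degrees) are evaluated, keeping the best strictly improving
   feasible move and halving both steps otherwise, down to
   `refine_min_step` (default 0.25).

`brute_force_plan()` enumerates the identical candidate set with a plain
nested loop and no short-circuiting; on shared settings it must return
the identical trajectory, which the tests assert. The screw-size
recommendation (largest standard diameter at or below 80% of the
narrowest-section caliper width; largest standard length at or below 80%
of the bony chord along the pedicle axis) is a heuristic of this
package, provided for workflow parity — no sizing formula is disclosed
by the reference software.

## The T' osteoporosis score

The clinical DXA T-score is transplanted onto CT values through the
linear CT-BMD relation:

$$T' = \frac{\text{measured CT value} - \text{reference mean}}
{\text{reference SD}},$$

with osteoporosis at $T' \le -2.5$. The threshold is inclusive (the
defining formula uses $\le$); boundary behavior is unit-tested. The
reference population is user-supplied or computed from untreated
vertebral means with the $n-1$ standard deviation. Group statistics
transform linearly: a group mean/SD maps to T' mean
$(m - \mu_\text{ref})/\sigma_\text{ref}$ and T' SD
$s/\sigma_\text{ref}$. When reproducing printed tables from rounded
group means, agreement to about 0.01 in T' is the attainable precision.

## The synthetic vertebra phantom

`generate_phantom()` voxelizes an idealized geometric vertebra on a
regular grid (default 0.5 mm isotropic): an elliptic-cylinder body
(half-axes 18 x 14 mm, height 30 mm) with a 1.5 mm cortical shell and
Gaussian cancellous interior; two oblique cylindrical pedicles (waist
radius 4.5 mm, flaring 20% toward the ends, convergence 12 degrees)
carrying cortical sleeves, merging anteriorly into the body through a
cortical junction collar and posteriorly into a cortical block standing
in for the lamina/spinous mass; a spinal canal (radius 5.5 mm) between
them; and one-voxel-thick narrowest-section ROI disks at the analytic
pedicle waists. Default dimensions are sized so the study's unified
6 x 30 mm screw fits through either pedicle. Default HU values
(cortical 3200, cancellous 2650 +/- 50, soft tissue 50) put the
bone-average on the high micro-CT scale of the decalcification study the
phantom emulates (whole-vertebra means around 2770 HU); they are chosen
to be plausible, not fitted to specimens.

Cancellous noise is i.i.d. Gaussian per voxel, seeded; identical spec
and seed give bit-identical volumes. The noise field is generated on one
half-grid and mirrored, so a corridor-free phantom is *exactly* mirror
symmetric about the midline — which turns left/right symmetry of the
planners into an exact test. An optional planted corridor adds an HU
boost to bone voxels inside a stated cylinder, giving a recoverable
ground-truth optimum.

Decalcification — an in vitro EDTA treatment in the emulated study — is
modeled as uniform multiplicative attenuation of bone HU toward water
(0 HU): `HU_new = f * HU` on bone labels, `f` in [0, 1], 1 = untreated.
This is exactly the linear CT-BMD premise; EDTA chemistry is out of
scope. Linearity gives a closed-form calibration: the factor hitting a
target T' is `(ref_mean + target * ref_sd) / mean_bone_HU`, and applying
factors f1 then f2 equals applying f1*f2. Note the direction of the
convention: *smaller* factors mean *more* decalcification, so T' rises
with the factor and falls as decalcification progresses.

What the phantom does **not** emulate: trabecular microarchitecture
(the emulated study explicitly scopes this out), realistic vertebral
shape variation, spatially correlated noise, multi-vertebra anatomy, or
soft tissue beyond a constant background. Passing recovery tests on the
phantom therefore demonstrates correctness of the optimization and
constraint machinery under known ground truth — not clinical validity on
patient CT.

## Validation problem sizes

The test suite validates the planner stack on 0.5 mm phantoms
(roughly 90 x 110 x 70 voxels). Planner property tests run five seeded
phantoms with a planted corridor (2 mm offset from the pedicle axis,
radius 2.5 mm, +500 HU) using a coarse search grid (1.5 mm entry step,
10-degree cone, 2.5-degree angular step) so that the exhaustive oracle
enumeration stays around a thousand candidates per phantom; the
pattern-search stage then refines to 0.25 mm / 0.25 degrees and must
recover the planted corridor within 2 mm and 5 degrees. Coarser 1 mm
phantoms back the brute-force voxel-classification oracles. The default
(finer) search settings remain the planner's production configuration.

## Numerical choices and degenerate inputs

* Trilinear interpolation for HU and distance-map reads; nearest-voxel
  lookup for labels.
* Exact anisotropic Euclidean distance transform (separable
  lower-envelope algorithm) with a one-voxel background pad, so masks
  touching the array edge behave as if surrounded by exterior.
* World frame fixed RAS-like (x left-to-right, y posterior-to-anterior,
  z caudal-to-cranial); voxel indices 0-based; all geometry in world mm.
* Pedicle axis = principal eigenvector of the pedicle voxel covariance,
  oriented toward the body centroid; disconnected pedicle labels are
  rejected (6-connectivity flood fill).
* Minimum-section sweep uses one-voxel-thick slabs at half-voxel steps,
  excluding end slabs; exact area ties resolve to the slab closest to
  the pedicle mid-length.
* Empty masks, out-of-grid samples, infeasible decalcification targets
  and degenerate projections raise explicit errors; merely infeasible
  trajectories return reports, never errors.

## Known limitations

* HU values are taken at face value; no reconstruction-kernel or
  scanner calibration model is applied.
* Medial vs lateral pedicle walls are treated symmetrically — there is
  no asymmetric safety margin.
* The screw is a geometric cylinder: no thread, insertion-torque or
  microfracture mechanics, and no pull-out force prediction from HU.
* Labels are inputs (or phantom-generated); the package does not segment
  vertebrae from raw CT.
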