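---
title: "Automated alpha-angle measurement: model, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated alpha-angle measurement: model, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camangle)
```

## The measurement problem

Cam-type femoroacetabular impingement is characterised by aspherical bone
excess at the femoral head–neck junction. The clinical quantifier is the
alpha angle: on a radial image through the femoral neck axis, the angle at
the head centre between the neck axis and the ray to the first point where
the bone contour exceeds the best-fit head circle. Manual measurement
requires an observer to reformat radial planes, fit the circle, mark the
neck centre and the exceedance point — a procedure with substantial intra-
and inter-observer variability. This package automates the measurement in
3D, starting from the one input a segmentation pipeline provides: a binary
mask of the proximal femur.

## The automated model

All stages operate in world millimetres (voxel index times spacing plus
origin; a voxel's position is its centre).

**Surface.** The binary occupancy grid is smoothed with a small separable
Gaussian (default sigma = 1 voxel) and iso-surfaced at level 0.5 by
marching tetrahedra. Smoothing makes the level-0.5 surface interpolate the
voxel staircase: on a digital sphere the mesh area converges to the
analytic value within a few percent at 1 mm spacing, and surface positions
are unbiased up to a curvature term of order sigma squared times curvature
(about 0.1 mm for a 24 mm head). Only the largest connected component is
kept.

**Initial landmarks.** The femoral head hosts the largest sphere inscribed
in the bone, so its centre and radius come from the global maximum of the
exact Euclidean distance transform (ties broken toward the lowest (x, y, z)
index, making the choice deterministic). The approximate neck axis is the
principal direction of the foreground voxels in a spherical shell at 1.1–2.0
head radii, computed about the head centre (not about the shell's own mean:
the offset of the neck/shaft from the centre then dominates the second
moment, which keeps the direction stable even for short, thick necks where
centred PCA is ill-conditioned). The sign points toward the shell's centre
of mass, i.e. away from the head apex. These landmarks only need to land
inside the refinement basins of the next stages; on phantoms they are
accurate to well under a voxel and a few degrees.

**Head/neck partition.** Vertices within 1.10 head radii of the centre are
head; remaining vertices with axial projection in 0.8–2.2 head radii and
axial distance at most 1.2 head radii are neck. The three thresholds are
exposed in `alpha_control()`; they are deliberately loose, since the sphere
fit is robust and the neck search filters its own cross-sections.

**Sphere refinement.** RANSAC with 2000 four-point hypotheses, each solved
exactly through the circumsphere linear system (near-coplanar quadruples
rejected), inlier threshold `max(0.75 mm, 2% of radius)`, followed by one
least-squares polish + re-selection round. The sampler uses an explicit
seed and restores the caller's RNG state, so runs are bit-reproducible.

**Neck axis.** The neck plane is the station (every 1 mm along the current
axis) whose mesh cross-section restricted to neck triangles has minimal
circumference. A valid section must be a closed, nearly circular ring:
candidates must wind at least 90% of the way around the axis, have total
segment length at least 97% of the circumference of a circle at their mean
radius, and radial eccentricity (sd/mean of radii) at most 0.15 — ragged
rings straddling the label boundary and oblique clips of the
intertrochanteric flare would otherwise fake smaller circumferences. If no
ring passes, the filters relax in two steps rather than failing outright.
The refined direction runs from the sphere centre to the ring centroid; the
procedure iterates (re-slicing normal to the new axis) to a fixed point,
tolerance 0.5 degrees, at most 10 iterations. On cylindrical-neck phantoms
it converges in 2–3 iterations to within 0.1 degrees and recovers the
circumference within a fraction of a percent, with a basin of attraction
wider than 10 degrees of initial axis error.

**Roundness map and optimal cut.** Rays from the sphere centre sample the
surface radius over azimuth (matching the slice group, default 120 slices =
3-degree steps over the full circle) and polar angle theta from the
neck-axis direction (0.5-degree bins over (0, 175]). rho = radius / fitted
head radius. Alpha per azimuth is the cut `theta_c(phi)` minimising

    sum_phi D(phi, theta_c(phi)) + lambda * sum_phi |theta_c(phi+1) - theta_c(phi)|

D counts, per azimuth, supra-threshold cells (rho > 1 + tau) strictly above
the cut weighted `w_head = 10` and sub-threshold cells at or below the cut
weighted `w_neck = 1`; the penalty `lambda = 2` per polar bin of cut change
between neighbouring azimuths enforces smoothness; the azimuth domain is
circular. The programme is solved exactly by dynamic programming over all
starting states with O(n) L1 distance transforms; ties break toward the
lower polar bin, so at lambda = 0 the cut reduces exactly to independent
per-column minimisation (verified against a brute-force oracle in the
tests) and for large lambda it degenerates to the best constant cut.

The tolerance tau is `max(0.6 mm, half the voxel diagonal)` of radial
excess, divided by the head radius. The floor reflects sub-millimetre
imaging resolution: without it, voxelisation ripple (sub-half-voxel)
triggers false exceedance. This tolerance is the main systematic of the
method: on a perfect sphere-plus-cylinder geometry the cut sits where the
neck cone crosses `rho = 1 + tau`, i.e. at `asin(sin(alpha_true) / (1 +
tau))` — about 1.5–2.6 degrees below the true baseline across neck/head
ratios 0.5–0.8 at 1 mm voxels. We report the cut angle as measured, as a
manual reader applying the same exceedance rule would.

**Convention.** Theta is measured from the neck-axis direction, so the cut
angle *is* the alpha angle, with no offset convention. The exceedance point
is reached travelling from the head apex toward the neck; the cut
correspondingly selects the largest aspherical polar angle (the cam's
head-side boundary). This traversal direction is the single most
consequential convention in the package and is used identically in the 3D
cut, the 2D construction and the phantom ground truth, which makes the
three commensurable.

**Azimuth convention.** Azimuth 0 is anterior (the world +x direction
projected orthogonal to the axis), 90 superior, 180 posterior, 270
inferior, viewed along the axis from head to neck. Slices are half-planes:
a clinical radial image corresponds to the pair phi / phi + 180, and alpha
is reported per half-plane (anterior and posterior alpha differ
clinically); `alpha_profile_pairs()` provides the max-of-pair view. The
seven named planes map to azimuths 0, 30, ..., 180. A 180-degree legacy
span with 7 slices reproduces exactly the named planes.

## The manual construction

`notzli_alpha_2d()` implements the classical 2D procedure as an independent
oracle: robust algebraic circle fit on the head arc (one trimming pass at
twice the median absolute residual), neck centre at the narrowest
cross-section along the neck direction (ties toward the head; the search is
confined to twice the fitted radius so the distal shaft, whose oblique
sections can be narrower, is excluded), first exceedance at `r + 0.6 mm`.
It consumes either exact analytic phantom contours or contours extracted
from the mask itself (`mask_slice_contour()`), which is how
manual–automated concordance is tested at both infinite and voxel
resolution.

## The phantom generator

`generate_phantom()` voxelises (centre-in-solid) the union of a spherical
head, a cylindrical neck along an oblique axis, and a broader
shaft/metaphysis cylinder at a 130-degree neck-shaft angle that overlaps
the neck end (real anatomy has no exposed neck end-cap; an abrupt cap would
also present an artificial minimal ring to the neck search). Default scale
is an adult hip: head radius 24 mm, neck radius 16 mm (baseline alpha
41.8 degrees), neck length 30 mm, 1 mm isotropic voxels, about 10^6-voxel
grids. The cam bump multiplies the head radius by `1 + h * w(theta, phi)`
with `h = cam_height_frac` and `w` a separable window that is exactly zero
on the region boundary and exactly one on a central plateau
(raised-cosine tapers over 50% of the polar span and 20% of the azimuth
span). The plateau is the deliberate design choice: with it, the
ground-truth first-exceedance angle equals `cam_theta_max` for every
azimuth on the plateau regardless of the detection tolerance, so recovery
can be scored against an unambiguous constant. A pure taper with no
plateau would make the exceedance angle drift with azimuth under any
finite tolerance, leaving nothing sharp to recover. Near the azimuth span
edges the bump necessarily vanishes (continuity), so edge azimuths are
excluded from cam-recovery scoring; the plateau covers 80% of the span.
`analytic_alpha(spec, tol_mm)` gives the closed-form profile at any
detection tolerance, including the taper drift.

What the phantoms emulate: correct topology and scale, anisotropic-capable
voxelisation, cam bumps of controllable position/extent/height, optional
seeded Gaussian surface jitter. What they do not emulate: grayscale MRI
contrast and segmentation errors, cortical/trabecular structure, the
acetabulum, and real anatomical shape variation (fossa, trochanters,
aspherical "normal" heads). Passing phantom tests therefore demonstrates
the geometry engine is correct at imaging resolution, not that segmentation
masks of arbitrary quality yield clinically valid angles.

## Numerical choices and degenerate inputs

* Grids are aligned so the head centre falls on a voxel centre, making
  rotational-symmetry tests exact and runs deterministic.
* The distance-transform maximum tie-breaks to the lowest index;
  the DP tie-breaks to the lower polar bin; the neck-ring tie
  (cylinders have constant circumference) resolves to the first minimal
  station, nearest the head, matching the manual convention.
* Azimuth columns with no sampled cells get zero data cost and are
  interpolated by the smoothness term, flagged `"extrapolated"`.
* Empty masks, 4D volumes, oblique affines, surfaces under 100 vertices,
  empty head/neck partitions, missing rating cells and degenerate
  zero-variance paired tests all raise typed conditions
  (`camangle_error` subclasses) rather than generic errors.
* Problem sizes: validation runs use 1 mm adult-scale phantoms (~10^6
  voxels, ~10^5 triangles), 120 azimuths x 350 polar bins, 2000 RANSAC
  hypotheses and 200 simulated rating tables — each full pipeline run takes
  a few seconds on one CPU.

## Agreement statistics

`icc_absolute()` is fixed to the two-way random-effects, absolute-agreement,
single-measure ICC — the standard model when the same raters rate all units
and systematic offsets must count against agreement. Units are (hip, plane)
pairs by default (19 x 7 = 133 in the canonical design), optionally per-hip
means. The 95% interval is the standard F-based interval with
Satterthwaite degrees of freedom; the p-value is the F test of the
between-subjects effect. Mean squares come from `stats::aov`; the test
suite checks the estimate against an independent sums-of-squares oracle to
1e-10, and simulation shows the generating intraclass correlation is
recovered within a few thousandths on average over 200 tables.
Reliability bands follow the conventional rule (>0.9 excellent, 0.75–0.9
good, 0.5–0.75 moderate, <0.5 poor). `bland_altman()` uses the sample SD
with 1.96 limits; `paired_t()` flags zero-variance differences as
degenerate instead of erroring. Percentiles use linear interpolation
between order statistics.

## Design decisions that were genuinely open

* **"Circle with the smallest circumference"** is read as the
  minimal-perimeter planar cross-section of the neck surface (not an
  inscribed or fitted circle); the ring centroid stands in for the circle
  centre. The ring-quality filters above are this package's addition; the
  minimal-perimeter criterion alone is degenerate on meshes with label
  boundaries.
* **Axis refinement** is run as a fixed-point iteration rather than a
  single pass; a single pass is the first iterate, and the iteration count
  is reported in the result metadata.
* **The cut's cost function** (asymmetric misclassification counts + L1
  smoothness) is one concrete instantiation of a boundary-finding cost on
  a roundness map; all four constants are exposed in `alpha_control()`.
  Behavioural checks (lambda = 0 reduction, large-lambda constancy,
  monotonicity in cam extent, phantom recovery) pin its behaviour rather
  than any particular reference implementation.
* **120 slices over 360 degrees** of half-planes is the default sampling;
  whether a dense radial group should span 360 degrees of half-planes or
  180 degrees of full planes is ambiguous in clinical practice, so both
  modes exist (`span_deg`).
* **Anatomy defaults** (24/16 mm head/neck, 130-degree neck-shaft angle,
  metaphysis broader than neck but narrower than head) are plausibility
  choices for an adult hip at desk-scale grids, not estimates from any
  cohort.

## Known limitations

* The tolerance-induced negative bias of 1.5–2.6 degrees described above is
  inherent to any exceedance rule with a resolution floor; comparisons
  between methods should use the same tolerance.
* The pipeline assumes one proximal femur per mask with a roughly spherical
  head; severely deformed heads (e.g. late Perthes) violate the RANSAC
  inlier assumption and will be rejected rather than mis-measured.
* Alpha angles at azimuths whose rays graze the metaphysis (low polar
  angles near the inferior side) rely on the cut's smoothness term; the
  clinically read range (anterior–posterior through superior) is unaffected.
* Observer-agreement tools handle exactly two raters per comparison; designs
  with more raters need repeated pairwise calls.
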