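# camangle

Automated measurement of the **alpha angle** — the standard quantifier of
femoral head–neck offset loss in cam-type femoroacetabular impingement
(FAI) — from 3D binary segmentation masks of the proximal femur, together
with the classical manual 2D construction and the observer-agreement
statistics used to compare raters and methods.

It is written for musculoskeletal imaging researchers who have proximal-femur
segmentations (e.g. from high-resolution hip MRI) and want reproducible,
observer-independent alpha angles on a dense radial slice group instead of a
handful of manually reformatted planes.

## The measurement

The alpha angle on a radial image is the angle at the femoral head centre
*hc* between the neck axis *hc → nc* and the ray to the point *A* where the
bone contour first leaves the best-fit head circle of radius *r*:

```
alpha = angle( A - hc , nc - hc ),   A = first point with |p - hc| > r(1 + tau)
```

For a spherical head of radius *R* joined to a cylindrical neck of radius
*r_neck*, alpha equals `asin(r_neck / R)`; a cam deformity (aspherical bone
excess at the head–neck junction) raises it.

The automated 3D pipeline mirrors the workflow of prototype software for
hip MRI post-processing:

1. **Surface** — iso-surface the mask at occupancy 0.5 (marching-tetrahedra,
   Gaussian-regularised) in world mm coordinates.
2. **Landmarks** — head centre and radius from the largest inscribed sphere
   (Euclidean distance transform); approximate neck axis from the principal
   direction of a spherical shell around the head.
3. **Partition** — label head and neck vertices by position relative to the
   landmarks.
4. **Sphere fit** — RANSAC over exact 4-point circumspheres with
   least-squares polish, robust to the cam and to the neck.
5. **Neck axis** — the planar cross-section of the neck surface with minimal
   circumference defines the neck plane; the axis is refined iteratively
   through the sphere centre.
6. **Roundness map** — surface radius / fitted head radius on a spherical
   grid (azimuth phi around the axis x polar angle theta from the axis),
   sampled by ray casting from the sphere centre.
7. **Optimal cut** — alpha per azimuth is the polar cut `theta_c(phi)`
   minimising an asymmetric misclassification cost (aspherical cells left on
   the head side weighted 10:1 against spherical cells on the neck side)
   plus an L1 smoothness penalty, solved exactly by dynamic programming on
   the circular azimuth domain. The seven named clinical planes (anterior …
   posterior through superior) are read off the profile.

Because no study imaging data are distributed, validation is built on
**parametric femur phantoms** (head, neck, tilted shaft, optional cam bump
of controllable polar/azimuth extent and height) with closed-form
ground-truth alpha profiles.

## Worked example

```r
library(camangle)

# a cam phantom: 24 mm head, 16 mm neck, cam up to 70 deg spanning 60 deg
# of azimuth at 15% height
spec <- femur_phantom(cam_present = TRUE, cam_theta_min_deg = 50,
                      cam_theta_max_deg = 70, cam_phi_min_deg = 0,
                      cam_phi_max_deg = 60, cam_height_frac = 0.15)
mask <- generate_phantom(spec, spacing_mm = 1)
fit  <- measure_alpha(mask, n_slices = 120, seed = 17, hip_id = "phantom-cam70")
fit
#> alpha_fit (hip 'phantom-cam70'): 120 radial slices
#>   head: radius 24.0 mm (95% RANSAC inliers); neck circumference 100.4 mm
#>   alpha: 39.5-69.5 deg (median 40.0)
round(coef(fit), 1)
#>           anterior  anterior-superior  superior-anterior           superior
#>               40.0               69.5               40.0               40.0
#> superior-posterior posterior-superior          posterior
#>               40.0               40.0               40.0
```

The baseline truth is `asin(16/24) = 41.8` degrees; the measured 40.0
reflects the deliberate 0.87 mm asphericity tolerance (half a voxel
diagonal) that keeps voxelisation noise from triggering false exceedance.
The cam reaches its 70-degree polar extent only across azimuths 0–60, so the
anterior-superior plane (azimuth 30) reads 69.5 while the others stay at
baseline. `plot(fit)` draws the roundness map with the cut overlaid;
`summary(fit)` adds the per-stage geometry.

Agreement statistics work on long-format tables (hip, plane, rater, alpha):

```r
tab <- simulate_rating_table(icc = 0.8, seed = 3)   # 19 hips x 7 planes x 2 raters
icc_absolute(tab, raters = c("rater1", "rater2"))
#> ICC (absolute agreement, single measures): 0.722 [0.629-0.794], p < 0.001
#>   moderate reliability; 133 units x 2 raters (two-way random effects, ...)
```

A thin command-line interface wraps the same functions:

```sh
inst/cli/camangle synth   --spec spec.json --spacing 1.0 --out phantom.nii.gz --truth truth.csv
inst/cli/camangle measure --mask phantom.nii.gz --out result.json --csv alphas.csv --n-slices 120 --seed 17
inst/cli/camangle compare --table measurements.csv --raters obs1,software --out agreement.json
```

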