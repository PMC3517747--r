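---
title: "Measuring tibiofemoral and patellofemoral 3D kinematics: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring tibiofemoral and patellofemoral 3D kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneekin)
```

## Overview

`kneekin` measures the relative 3-D pose of femur, tibia and patella from
segmented knee images acquired statically at several flexion angles. The
pipeline is anatomical-coordinate-system based: every quantity is defined
as a coordinate or angle in a frame constructed from the bone surfaces
themselves, so that repeated acquisitions of one knee are comparable
without any cross-acquisition registration. This vignette documents the
models, the conventions that were genuinely open choices, the numerical
details, and what the synthetic validation does and does not establish.

## Coordinate systems

**Tibial frame.** The origin is the area-centroid of the tibial-plateau
articular surface (area-weighted mean of triangle centroids). The axes
come from the principal axes of the plateau surface: the smallest-variance
direction is the plateau normal (z, proximal +), the largest in-plane
spread is medio-lateral (x, lateral +), and y = z × x points anterior.
Principal directions are sign-ambiguous, so signs are fixed against an
`orientation_hints()` record — two rough world-space directions
("proximal", "lateral") that any scan protocol provides; hints only need
to be within a hemisphere of the truth. For near-circular plateaus the two
in-plane eigenvalues approach each other and the eigenvector direction
becomes unstable; below a relative gap of 5% the medio-lateral axis falls
back to the lateral hint projected into the plateau plane, so that the
frame of one subject cannot flip between conditions.

Whether the anterior or posterior direction is y-positive is a pure
convention; `kneekin` uses anterior-positive throughout, and all
anterior–posterior (AP) outputs follow it.

**Patellar frame (PBCS).** Origin C at the centroid of the volume enclosed
by the closed patellar mesh (divergence-theorem integral — robust to
non-uniform meshing), long axis Py from the first principal direction
(superior +), Px medio-lateral (lateral +), Pz = Px × Py anterior. The
inferior patellar pole (IPP) is the mesh vertex minimizing the Py
coordinate.

**Surface versus vertex moments.** Frame axes are *not* computed from raw
vertex PCA. On meshes extracted from voxel data, vertex density depends on
the local surface orientation (staircase regions are oversampled), which
rotates unweighted eigenvectors by degrees. The tibial frame therefore
uses area-weighted surface moments, and the patellar frame and femoral
shaft axis use second moments of the enclosed solid, which are insensitive
to surface-sampling artifacts because signed staircase contributions
cancel. On clean parametric meshes all three definitions coincide to
numerical precision.

## Epicondylar axis and tibiofemoral kinematics

The femoral reference axis is a least-squares cylinder fitted to the
posterior condylar articular surfaces of both condyles jointly: minimize
Σ(dᵢ − r)² where dᵢ is the distance of point i to the axis. The axis is
parameterized as a two-parameter perturbation of an initial direction
(largest principal component of the points, or a user guess) plus a 2-D
anchor in the orthogonal plane; the radius is profiled out (for a fixed
axis the optimal r is the mean distance), and the reduced four-parameter
problem is solved by BFGS from an algebraic (Kasa) circle-fit start.
Exact synthetic cylinders are recovered to below 1e-6 in radius and
direction; the fit refuses fewer than 6 points and coplanar or collinear
point sets, and reports the RMS residual as a per-scene diagnostic.

The medial and lateral reference points are the area-centroids of the two
condylar surfaces projected orthogonally onto the axis; the central point
is their midpoint. Expressed in the tibial frame, the y-coordinates of the
three points are the AP positions, and the axial rotation is the signed
transverse-plane angle of the medial→lateral vector against x, internal
rotation positive, range (−180°, 180°].

Each acquisition uses its own tibial frame. Comparability across
conditions therefore rests entirely on the determinism and tie-break rules
of the frame construction, which is why those rules are explicit. Pose
differences (`tf_delta`) are antisymmetric by construction and wrap
rotation differences into (−180°, 180°].

**Coupling of translation and rotation.** For a rigid epicondylar axis the
axial rotation and the differential AP translation of the two reference
points are the same degree of freedom: sin(rotation) =
(AP_lateral − AP_medial) / (2·d), with d the axial distance of each
reference point from the centre. The motion model therefore imposes the
two AP positions and *derives* rotation. The default condylar offset
d = 28.65 mm makes 1 mm of differential translation correspond to 1° of
rotation, so the default healthy pattern (lateral 14 mm and medial 4 mm of
posterior translation over 0→90°) implies exactly 10° of external
rotation.

## Patellofemoral parameters

* **Patellar height**: Euclidean distance from the IPP to the line through
  the tibial origin along x (the tibial medio-lateral axis). Units mm.
* **Patellofemoral angle**: arccos(Py · F) with F the femoral shaft axis
  (first principal direction of the shaft, proximal +), in [0°, 180°];
  with both axes oriented superiorly it increases with flexion. Note the
  measured angle is unsigned: for condition means near 0° the sampling
  distribution folds at zero and cohort means are biased upwards; the
  study conditions of interest (30°, 90°) are far from the fold.
* **Patellar tilt**: the angle, in the PBCS transverse (x–z) plane,
  between the trochlear reference line and Px; positive when the angle
  opens medially (patellar lateral edge posterior relative to the
  trochlear line).
* **Patellar shift**: (C − Pmax) · x_t, lateral positive, where Pmax is
  the deepest-groove reference vertex (below).

**Trochlear landmark operationalization.** The groove landmarks are the
genuinely open design area. The naive construction — split trochlear
vertices by the sign of PBCS x and take per-facet vertices of minimal |x|
— fails in exactly the configurations of interest: a lateral shift of a
few millimetres moves the x = 0 plane onto the lateral facet, so both
chord endpoints land on one facet and the "tilt" reads the facet slope
instead of the patellar rotation; and on voxel-derived surfaces a chord
between two single vertices is unstable by many degrees. `kneekin`
therefore anchors the groove midplane at the *sulcus-floor curve* and
solves floor and groove orientation self-consistently:

1. Candidate groove rotations are scanned (±40° in 5° steps). For each,
   the floor is the per-slab (2.5 mm along Py) posterior extreme in the
   rotated frame; candidates are scored by floor straightness (MAD of its
   medio-lateral positions), posteriority, and the requirement that facet
   surface exists on both sides — a facet rim line is straight and can be
   posterior-most under extreme tilt, but is one-sided.
2. From the best candidate, the estimate is refined: each facet is reduced
   to a binned midsurface profile (mean medio-lateral position and mean
   depth per 1 mm bin over the band 3–7 mm from the midplane, clear of the
   smoothing-rounded crease and of the facet rims) and fitted by a line;
   the mean of the two arm angles updates the rotation. Three iterations
   suffice.

On clean meshes the resulting reference direction equals the chord through
the per-facet vertices nearest the midplane (which are still reported as
Pmin1/Pmin2, with Pmax the floor vertex farthest from the PBCS y–z plane),
and imposed tilts are recovered exactly at least to ±36°, beyond the facet
opening angle. Slab boundaries are rounded to 9 decimals before binning
(floating-point jitter must not split a slab), and floor picks from
end-rim slabs are discarded by a 2 mm posteriority filter. If the patellar
midplane lies further from the trochlear surface than half the trochlear
width, the patella is declared dislocated and the scene is reported as an
error rather than a number.

## Geometry input

Voxel input is NIfTI (axis-aligned, positive-diagonal affine; integer
labels; spacing from the affine). Surfaces are extracted per label as the
0.5-isosurface of the label's indicator field by marching tetrahedra (six
tetrahedra per cell around the main diagonal, so facets match across
cells), welded, cleaned of degenerate faces, and oriented outward. Two
pre-contouring options matter:

* **Indicator smoothing** (default on): a 3×3×3 box mean. Binary
  isosurfaces overestimate area by ~25–30% (staircase); with smoothing the
  area of a voxelized sphere is within a few percent of the analytic value
  and the RMS surface distance is a small fraction of a voxel. Structures
  thinner than about two voxels would be erased; the synthetic shells are
  generated 2 mm thick at 1 mm spacing for this reason.
* **Continuous upsampling** (`upsample` in `extract_surface()`): the
  indicator is tri-linearly interpolated onto a finer grid *without*
  re-thresholding before contouring, so the finer marching samples the
  same interpolated surface with shorter chords. (Re-thresholding labels
  onto a finer grid — `trilinear_upsample()`, provided for label-volume
  workflows — re-quantizes the surface and does not by itself improve
  reconstruction error.)

Tri-linear interpolation acts per-label on indicator fields, never on the
raw label integers, to avoid blending across label identities.

## The synthetic knee generator

The generator is the validation instrument: every measured quantity has an
imposed twin. Structures are built parametrically in the tibial reference
frame — elliptical plateau (35 × 25 mm semi-axes), condylar cylinder
(radius 20 mm, band half-width 10 mm) whose axis passes through the
imposed medial/lateral AP positions, femoral shaft tube (radius 14 mm,
length 110 mm) along the flexion direction, V-profile trochlear groove
(half-width 12 mm, 30° facet opening) with its floor offset by the imposed
shift, and a triaxial patellar ellipsoid (semi-axes 20, 25, 10 mm) placed
so its inferior pole sits at the imposed height, its long axis at the
imposed patellofemoral angle, and its body rotated about the long axis by
the imposed tilt. Meshes use symmetric quad tessellation (centroid fans)
so that the solids inherit the symmetries of the shapes; a fixed diagonal
split would bias the solid moments measurably. The pole-to-floor gap
defaults to 11 mm so that, across the default motion range, the trochlear
shell never intersects the patellar body — voxelized scenes then have
disjoint bone labels (in overlap-pathological configurations the patella
is voxelized last as a safety net).

Cohorts draw each parameter per subject and condition from normal
distributions centred on the group motion model, with the study
calibration SDs for the four patellofemoral parameters and a configurable
between-subject SD (default 1.5 mm) for the condylar AP positions; an
optional shared subject-level intercept (default SD 0) models
within-subject correlation across conditions. Sampling order is fixed, so
a seed reproduces a cohort bit-identically.

The default healthy model starts internally rotated (5°) and rolls back
with flexion, lateral more than medial (14 vs 4 mm by 90°, 10° external
rotation), and is unaffected by flexor activity. The default PCL-deficient
model matches the healthy one at 0° and 30°, then translates the medial
condyle 6 mm anteriorly from 30° to 90° (8 mm under flexor activity) with
a nearly constant lateral condyle and reduced external rotation. The
tibiofemoral magnitudes are generator choices made once; the
patellofemoral means and SDs are the published per-condition calibration.

**What passing tests show — and what they do not.** The generator emulates
segmented geometry with between-subject parameter variation; it does not
emulate segmentation errors, partial-volume effects, cartilage (landmarks
are bone-surface based), intensity artifacts, or realistic bone shape
variation. Recovery within tolerance on generator knees therefore
validates the measurement *logic* (frames, fit, landmarks, signs) and its
discretization robustness (via the voxel path at 1 mm), not performance on
clinical segmentations.

## Statistics

Summaries are per group × condition × parameter sample means and SDs
(n − 1). Comparisons are two-sided Student t-tests: paired across
conditions within a group (df = n − 1), two-sample between groups at a
condition. The two-sample default is the pooled-variance statistic,
matching the era of the desktop statistics packages the protocol used;
Welch is available via `var_equal = FALSE`. Zero-variance paired
differences yield an explicit degenerate result (identical conditions
return the clean null t = 0, p = 1). No multiplicity correction is
applied, mirroring the original analysis; the mixed-model factor analysis
of the original study is an off-the-shelf regression and is intentionally
out of scope.

A calibration caveat that the acceptance suite makes explicit: with
independent normal draws at the published per-cell means and SDs, the
between-group two-sample test at 90° has limited power (the tilt
separation corresponds to a noncentrality of ≈ 2.5, the shift separation
≈ 1.1 at n = 20 vs 12), so the full published significance pattern is not
reproducible in a large fraction of simulated cohorts from the printed
summary statistics alone. The corresponding acceptance expectation is
asserted at its stated threshold and fails honestly; the package reports
the observed replicate fraction rather than adjusting the generator.

## Numerical choices and problem sizes

* Frame orthonormality is enforced to 1e-9; right-handedness exactly
  (third axis is the cross product).
* Cylinder fit: BFGS, relative tolerance 1e-15, at most 500 iterations;
  non-convergence with a non-trivial residual is an error.
* Rotation wrap-around: angles live in (−180°, 180°].
* Vertex welding after isosurface extraction uses a 1e-6 mm key; zero-area
  triangles are dropped everywhere.
* Test problem sizes were chosen for sub-minute feedback: spheres of
  radius 10 mm at 1–2 mm spacing for the surface oracles; one full knee
  voxelized at 1 mm for the volume path; cohorts of 2–20 subjects for
  pipeline tests; 10,000 replicates for the paired-t type-I check and 50
  seeded cohort replicates for the significance pattern.

## Known limitations

* Single frame convention per bone; no alternative (e.g. malleolar-axis)
  tibial frames.
* Only AP translation and axial rotation are reported tibiofemorally — no
  six-degree-of-freedom joint decomposition.
* The patellofemoral angle is unsigned (fold at 0°).
* Landmarks are bone-surface, not cartilage, based.
* NIfTI input must be axis-aligned; oblique acquisitions need resampling
  upstream.
* The trochlear landmark search assumes a single-grooved surface; a
  dysplastic (flat or convex) trochlea would need a different reference.
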