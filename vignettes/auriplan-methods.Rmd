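---
title: "Methods: mirror-symmetry planning, marker guidance and outcome evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mirror-symmetry planning, marker guidance and outcome evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

`auriplan` implements the geometric core of a computer-assisted workflow for
reconstructing a missing or underdeveloped external ear (microtia/anotia)
from surface scans of the patient's head:

1. **Planning.** The healthy contralateral ear is mirrored across the
   head's midsagittal plane; the mirrored copy — the *specular ear* — is
   the target shape and position for the reconstruction.
2. **Guidance.** During surgery, a patterned reference cube rigidly linked
   to the skull through a dental splint is observed by a tablet camera;
   solving the cube pose and composing it with the fixed splint and plan
   transforms places the planned ear in the camera frame.
3. **Evaluation.** The postoperative scan is rigidly registered onto the
   plan using the facial surfaces that surgery does not alter, and the
   outcome is quantified by signed point-to-surface distance maps, region
   summaries and ear length/width morphometrics.

All computation is in the RAS (right-anterior-superior) frame in
millimetres; files declaring LPS are flipped on ingest. Transforms are 4x4
homogeneous matrices acting on column points, composed so that
`iso_compose(A, B)` applies `B` first. This convention is fixed once so
that transform chains are testable.

## Midsagittal plane estimation

The mirroring plane is rarely given explicitly, so
`estimate_sagittal_plane()` estimates it as the plane minimising the
mirror-registration residual:

* **Initialisation.** From landmarks when supplied — the perpendicular
  bisector of a left/right pair (suffix convention `_L`/`_R`), or, for
  midline points, the mesh's least-variance axis orthogonalised against
  the midline direction. Without landmarks, the principal axis of least
  vertex variance through the centroid is used; for a head this is the
  left-right axis.
* **Refinement (mirror-ICP).** A seeded random subsample (default
  `min(5000, n)` vertices) is reflected across the candidate plane and
  rigidly registered back onto the full mesh by ICP. The composition of
  reflection and rigid correction is a reflective isometry; its mirror
  plane (eigenvector of the linear part at eigenvalue -1, offset half the
  normal component of the translation) becomes the next candidate.
* **Convergence.** Normal change < 0.01 degrees and offset change
  < 0.01 mm, at most 50 outer iterations; non-convergence raises an error
  carrying the last residual.

The subsample seed is a caller-supplied argument so runs are reproducible.
The plane is always an explicit, overridable input to the mirroring step
itself (`make_specular_ear()`), never a hidden state. Whether a clinical
plan mirrors the full head or only an ear crop is workflow-dependent; both
are supported, and the crop-then-mirror route is the default in the CLI
because it avoids dragging scanner artefacts from the far side of the head
into the plan.

## Rigid registration

`rigid_from_correspondences()` is the weighted Kabsch/Umeyama closed form:
SVD of the weighted cross-covariance, with the smallest singular direction
negated whenever the raw solution would be a reflection — a registration
must never mirror anatomy. Degenerate (collinear) configurations raise an
error rather than returning an arbitrary rotation.

`icp()` iterates: true point-to-surface foot points on target triangles
(computed by a compiled, grid-accelerated point-to-triangle query;
equidistant foot points resolve to the lowest face index for determinism),
rejection of correspondences above a residual percentile (default 90), and
the closed-form fit. The RMS is non-increasing by construction: a step
that would raise it is rejected and iteration stops. Defaults are
`max_iter = 100`, `tol_mm = 1e-4` (minimum RMS improvement). These are
deliberate, reproducible stand-ins for an interactive alignment; the exact
settings used in any given clinical workflow are generally unrecorded, so
every knob is exposed and reported in the result object.

Masks implement "register on the surfaces surgery does not change": the
union of spheres (default radius 25 mm) centred on named landmarks — eyes,
forehead, nose — restricted to the source vertex set. Convergence of this
plain foot-point iteration is linear and can be slow on smooth surfaces
(tangential sliding is weakly constrained); with a few hundred masked
points, a thousand iterations cost about a second, so the package favours
the simple, provably monotone scheme over point-to-plane linearisations.

## Marker pose and the guidance chain

The reference marker is a cube (default side 30 mm) with four corner
points per face, ordered counter-clockwise seen from outside, starting at
the face's `+e1+e2` corner — a fixed convention required to fabricate and
consume observations unambiguously. Pattern recognition is deliberately
out of scope: the boundary is `(face, corner, pixel)` records, which the
synthetic scene generator produces with back-face culling and optional
pixel noise.

`estimate_marker_pose()` minimises pixel reprojection error over the
6-dof pose by damped least squares: Gauss-Newton steps with a Levenberg
fallback (lambda starts at 1e-3, x10 on failure, /10 on success, at most
100 iterations, convergence when the RMS change falls below 1e-10 px).
Initialisation is a planar-homography pose on the most-observed face
(DLT, then orthonormalisation of the rotation by SVD); if a noisy
homography decomposes to a pose behind the camera, the solver restarts
from a frontal scale-from-spread guess. The camera is a pinhole with
optional radial distortion `(k1, k2)`.

`compose_guidance()` chains camera-from-marker, marker-from-splint,
splint-from-head and head-from-earplan into the rendering pose. The
silhouette check projects a mesh under two poses, resamples the 2D
convex-hull contours by arc length and returns the symmetric mean
nearest-point distance — zero exactly when the silhouettes coincide. For
a pure lateral shift this metric is bounded above by the image-space
shift `fx * dx / z` and deliberately reports the mean contour
discrepancy, not the worst case. Tracking status is a threshold rule on
reprojection RMS (default 2 px, inclusive: RMS equal to the threshold
still counts as tracked) plus marker visibility, mapping to the green/red
frame of the guidance display.

## Distance maps and morphometrics

`signed_distance_map()` measures each test-mesh vertex against the
nearest point on the reference *surface* (not nearest vertex). The sign
is taken from the outward-normal side of the nearest reference triangle:
positive outside, so a swollen (inflated) ear reads positive against the
plan. The reference model therefore defines the sign, and the headline
map is computed from the postoperative scan onto the plan. Summary
statistics follow the reporting convention of outcome studies: mean and
SD are over per-vertex absolute distances (population SD, divide by n),
with signed min/max retained. Degenerate (zero-area) faces — common in
scanner exports — are kept in the mesh but flagged and skipped by all
distance queries.

Ear metrics follow the clinical definitions: **length** is the longest
dimension — the 3D caliper diameter, computed as the exhaustive maximum
pairwise vertex distance (the maximum is attained on convex-hull
vertices; the compiled O(n^2) search is exact and fast at ear-crop
sizes). **Width** is ambiguous in the literature ("the shortest metric in
the perpendicular direction"); the package defaults to the standard
auricular reading — the extent along the unique direction orthogonal to
the length axis within the ear's least-squares best-fit plane — and
offers the literal minimal-perpendicular-extent reading behind
`width_rule = "min_perpendicular"`.

`compare_to_plan()` chains masked ICP, the signed map, region summaries,
ear-crop morphometrics (final minus specular differences) and an ear-only
ICP whose rotation is decomposed about the axial (superior-inferior)
axis — the residual degree of freedom clinically hardest to control.
Every stage labels its errors with the stage name, and the whole report
serialises to schema-versioned JSON.

## Synthetic data: what it emulates and what it does not

The generator exists so the entire pipeline is testable with known ground
truth and no clinical data. `make_head()` builds a closed, exactly
mirror-symmetric head: a UV sphere (poles on the superior-inferior axis;
the longitude count is a multiple of 4 so the lateral directions fall on
vertices) scaled to ellipsoid semi-axes of 70 x 85 x 105 mm — a
child-sized head — with radial displacement fields adding a nose, two
brow bumps (so masked registration has features to lock onto) and a
schematic parametric ear on each side: an elliptical base pad (height 55,
width 30 mm, protrusion 12 mm) carrying a helix-like Gaussian ridge
(6 mm). The right ear is the exact mirror of the left by construction,
which is what makes specular-ear assertions exact to machine precision.
Microtia is emulated by regenerating the head with one ear's displacement
suppressed — a smooth cap, a closed mesh, and bit-identical vertices
everywhere else.

`simulate_postop()` applies the perturbation vocabulary of real outcomes
— rotation about a chosen axis through the ear-region centroid (the axial
axis by default), translation, uniform inflation (scale 0.8-1.3) — with a
cosine ramp to identity over the outer 20% of the region radius so crease
artefacts do not dominate the distance maps, then adds independent
Gaussian vertex noise everywhere. Guard rails (|angle| <= 30 degrees,
scale in [0.8, 1.3]) keep scenarios in the clinically plausible range.

The generator is deliberately schematic: it does not model skin texture,
scanner-specific artefacts (holes, topological noise), facial expression
changes from intubation, or anatomically faithful auricular substructure.
Passing tests therefore demonstrate the correctness of the geometry
pipeline under controlled conditions, not robustness to every real-world
scan pathology.

## Numerical choices

* STL vertex merging is by exact coordinate match — no tolerance welding —
  so loading is deterministic; PLY is written at full double precision
  and round-trips exactly, STL at float32.
* Isometries are validated to `R'R = I` within 1e-8 on construction;
  planes keep unit normals to 1e-12.
* Closest-point ties resolve to the lowest triangle index; the uniform
  grid expands its search shell conservatively so results equal the
  brute-force scan.
* Random subsampling and noise always flow through caller-supplied seeds,
  and generator RNG state is isolated from the caller's stream.
* Degenerate inputs fail loudly with named conditions (empty crops,
  collinear correspondences, all-degenerate references, landmarks missing
  from a mask).

## Problem sizes

The test-suite and acceptance-script scenarios run at desk scale, chosen
to exercise every code path at comfortably interactive cost: heads of
~6,000 vertices (12,000 triangles), ear crops of ~150-200 vertices,
registration subsamples of 350-3,000 points, 50-scenario parameter
recovery sweeps, and 50-100 marker poses per batch. All scale linearly in
vertices (the closest-point grid makes queries effectively constant-time),
and the same code runs unchanged on full-resolution scanner exports.

## Known limitations

* Registration is rigid only; soft-tissue deformation (swelling, facial
  gestures) is measured by the distance map, never compensated.
* The mirror-ICP plane search is local; a grossly wrong initialisation
  (e.g. landmarks on the wrong axis) can converge to a non-sagittal
  symmetry plane.
* The pose solver assumes a calibrated pinhole camera with at most two
  radial distortion terms.
* The benchmark runner reproduces deposited-scan statistics only up to
  the alignment settings of the original interactive workflow, which are
  unrecorded; its default 0.3 mm tolerance reflects that.
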