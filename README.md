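# auriplan

Geometry toolkit for surgical planning, marker-based guidance and outcome
evaluation in external-ear (auricular) reconstruction.

Microtia — congenital underdevelopment of the external ear, up to complete
absence (anotia) — is treated by carving a cartilage framework and placing
it where a normal ear would sit. Two geometric questions decide the
outcome: *what shape and where* (planning), and *how far from the plan did
the result land* (evaluation). `auriplan` answers both from triangle-mesh
surface scans, plus the transform algebra that lets an augmented-reality
display show the planned ear on the patient through a camera:

* **Planning** — estimate the midsagittal plane of a head mesh and mirror
  the healthy ear across it. The mirrored copy (the *specular ear*) is the
  target shape in its target position.
* **Registration** — closed-form rigid fits from point correspondences
  (Kabsch, reflections excluded) and region-masked point-to-surface ICP,
  for aligning scans on the facial surfaces surgery does not alter.
* **AR guidance geometry** — pinhole projection, cube fiducial-marker pose
  estimation from pixel observations (homography init + damped least
  squares), the splint-anchored transform chain
  `T_cam_from_ear = T_cam_from_marker · T_marker_from_splint ·
  T_splint_from_head · T_head_from_earplan`, silhouette overlay error and
  tracking status.
* **Evaluation** — signed point-to-surface distance maps (positive =
  outside the reference surface), per-region summaries, ear length/width
  morphometrics (caliper length; width perpendicular to it in the ear's
  best-fit plane) and a one-call postop-vs-plan pipeline.
* **Synthetic data** — deterministic parametric heads with
  mirror-symmetric ears, microtia cases, perturbed postoperative scans
  with known ground truth, and synthetic marker scenes, so everything
  above is testable with no clinical data.

Meshes are read and written as STL (binary/ASCII), PLY and OBJ; landmarks
as 3D Slicer markups FCSV or JSON; everything computes in RAS millimetres.

## Worked example

```r
library(auriplan)

# a synthetic patient: ellipsoidal head, parametric ears, known truth
case <- make_head(synth_spec(seed = 1))
plan <- case$mesh
lm   <- case$landmarks

# 1. planning: sagittal plane, then the specular ear from the healthy side
pl <- estimate_sagittal_plane(plan, lm, seed = 1)
pl
#> <plane: n = (1.0000, 0.0000, 0.0000), d = -0.0000 mm>
spec_ear <- make_specular_ear(crop_region(plan, landmark(lm, "ear_L"), 44), pl)

# 2. a simulated postoperative scan: the ear placed with a residual
#    6-degree rotation about the axial axis, plus 0.3 mm scanner noise
po <- simulate_postop(plan, list(center = landmark(lm, "ear_R"), radius = 50),
                      list(axis = c(0, 0, 1), angle_deg = 6),
                      noise_sd = 0.3, seed = 2)

# 3. outcome evaluation: masked ICP -> signed distance map -> morphometrics
ev <- compare_to_plan(po$mesh, plan, lm, evaluation_config(icp_max_iter = 60))
ev
#> <plan_evaluation: |d| 0.29 +/- 0.35 mm (min -3.67, max 3.81)>
#>   ear length diff +0.32 mm, width diff -0.76 mm, axial rotation +5.89 deg
```

Reading the report: the global map sits at the 0.3 mm noise floor away
from the ear while the ear region averages 1.45 mm absolute deviation
(`ev$regions$ear$mean_abs`); the signed extremes (−3.67 / +3.81 mm) are
the opposite-signed anterior/posterior lobes that an axial rotation
stamps onto the ear; and the ear-only registration recovers the injected
6-degree rotation as +5.89 degrees.

The guidance chain closes the same way from synthetic camera data:

```r
cam <- camera_model(1000, 1000, 640, 360, c(1280, 720))
mk  <- marker_model(30)
scene <- synth_marker_scene(cam, mk,
           iso_compose(translation_isometry(c(10, -5, 300)),
                       rotation_isometry(c(0.3, 1, 0.2), 25)))
est <- estimate_marker_pose(scene$observations, mk, cam)
est
#> <registration: rms 4.341e-14, 2 iterations, converged>
tracking_status(TRUE, est$rms)
#> $status: "tracked"   $color: "green"
```

A thin command-line wrapper over these functions lives at
`inst/cli/auriplan.R` (`plan-mirror`, `register`, `evaluate`, `synth`,
`benchmark` subcommands), and `run_benchmark()` scores a directory of
deposited study models (plan, postoperative scan, phantom reference,
per-experiment ear crops) against expected statistics at a configurable
tolerance.

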