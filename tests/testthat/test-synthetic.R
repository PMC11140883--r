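test_that("generators are deterministic under a fixed seed", {
  sp <- synth_spec(seed = 5, asymmetry = list(scale = 1.05,
                                              rotation_deg = 3),
                   noise_sd = 0.2)
  h1 <- make_head(sp)
  h2 <- make_head(sp)
  expect_identical(h1$mesh$vertices, h2$mesh$vertices)
  expect_identical(h1$mesh$faces, h2$mesh$faces)
  expect_identical(h1$landmarks$points, h2$landmarks$points)
  po1 <- simulate_postop(h1$mesh, list(center = c(80, 0, 0), radius = 50),
                         list(angle_deg = 4), noise_sd = 0.3, seed = 9)
  po2 <- simulate_postop(h1$mesh, list(center = c(80, 0, 0), radius = 50),
                         list(angle_deg = 4), noise_sd = 0.3, seed = 9)
  expect_identical(po1$mesh$vertices, po2$mesh$vertices)
  # generator RNG does not disturb the caller's stream
  set.seed(1)
  a <- runif(1)
  set.seed(1)
  invisible(make_head(synth_spec(seed = 99, noise_sd = 0.1),
                      resolution = c(16, 24)))
  expect_identical(runif(1), a)
})

test_that("the symmetric head mirrors onto itself through the true plane", {
  h <- test_head()
  refl <- reflect_across_plane(h$ground_truth$sagittal_plane)
  mirrored <- apply_isometry(h$mesh, refl)
  dm <- signed_distance_map(mirrored, h$mesh)
  expect_lt(sqrt(mean(dm$per_vertex^2)), 1e-6)
  # specular of the left ear IS the right ear
  ear_L <- crop_region(h$mesh, landmark(h$landmarks, "ear_L"), 44)
  spec_ear <- make_specular_ear(ear_L, h$ground_truth$sagittal_plane)
  ear_R <- crop_region(h$mesh, landmark(h$landmarks, "ear_R"), 44)
  expect_lt(signed_distance_map(spec_ear, ear_R)$summary$mean_abs, 1e-9)
})

test_that("generated heads are closed, outward-oriented, edge-manifold", {
  h <- test_head()
  expect_gt(mesh_volume(h$mesh), 0)
  expect_true(is_closed_mesh(h$mesh))
  # every face consistently outward: signed volume of the reflected mesh
  # stays positive too (winding bookkeeping)
  refl <- reflect_across_plane(plane(c(0, 1, 0), 0))
  expect_gt(mesh_volume(apply_isometry(h$mesh, refl)), 0)
})

test_that("asymmetry perturbs only the right ear region", {
  sym <- make_head(synth_spec())
  asym <- make_head(synth_spec(asymmetry = list(scale = 1.1,
                                                rotation_deg = 5)))
  d <- sqrt(rowSums((sym$mesh$vertices - asym$mesh$vertices)^2))
  earc <- landmark(sym$landmarks, "ear_R")
  far <- sqrt(rowSums(sweep(sym$mesh$vertices, 2, earc)^2)) >
    sym$ground_truth$ear_region$radius
  expect_identical(max(d[far]), 0)
  expect_gt(max(d[!far]), 1)
  expect_false(is.null(asym$ground_truth$perturbation_applied))
})

test_that("microtia removal keeps the mesh closed and the healthy ear intact", {
  h <- test_head()
  mic <- make_microtia_case(h$mesh, "right", h$ground_truth)
  expect_true(is_closed_mesh(mic))
  expect_gt(mesh_volume(mic), 0)
  # healthy (left) side untouched, vertex for vertex
  left <- h$mesh$vertices[, 1] < -30
  expect_identical(mic$vertices[left, ], h$mesh$vertices[left, ])
  # the removed side lost its protrusion
  earc_R <- landmark(h$landmarks, "ear_R")
  expect_lt(max(mic$vertices[, 1]), earc_R[1] - 1)
})

test_that("zero perturbation reproduces the plan exactly", {
  h <- test_head()
  po <- simulate_postop(h$mesh, list(center = c(80, 0, 0), radius = 50),
                        list(angle_deg = 0), noise_sd = 0, seed = 1)
  expect_identical(po$mesh$vertices, h$mesh$vertices)
})

test_that("uniform inflation reads positive in the ear and zero elsewhere", {
  h <- test_head()
  earc <- landmark(h$landmarks, "ear_R")
  po <- simulate_postop(h$mesh, list(center = earc, radius = 50),
                        list(scale = 1.1), seed = 4)
  dm <- signed_distance_map(po$mesh, h$mesh)
  v <- po$mesh$vertices
  r <- sqrt(rowSums(sweep(v, 2, earc)^2))
  expect_gt(mean(dm$per_vertex[r < 40]), 0.5)
  expect_identical(max(abs(dm$per_vertex[r > 55])), 0)
  expect_error(simulate_postop(h$mesh, list(center = earc, radius = 50),
                               list(angle_deg = 40)), "30")
  expect_error(simulate_postop(h$mesh, list(center = earc, radius = 50),
                               list(scale = 0.5)), "scale")
})

test_that("marker scenes expose the expected faces and close the pose loop", {
  cam <- default_test_camera()
  mk <- marker_model(30)
  frontal <- synth_marker_scene(cam, mk, translation_isometry(c(0, 0, 300)))
  expect_identical(frontal$ground_truth$visible_faces, "z-")
  expect_identical(nrow(frontal$observations), 4L)
  corner <- synth_marker_scene(
    cam, mk, iso_compose(translation_isometry(c(0, 0, 300)),
                         rotation_isometry(c(1, 1, 1), 40)))
  expect_length(corner$ground_truth$visible_faces, 3)
  est <- estimate_marker_pose(corner$observations, mk, cam)
  expect_lt(est$rms, 1e-6)
  expect_error(synth_marker_scene(cam, mk,
                                  translation_isometry(c(0, 0, -300))),
               "visible")
})

test_that("reported deviation grows with the injected perturbation", {
  h <- make_head(synth_spec(), resolution = c(48, 72))
  earc <- landmark(h$landmarks, "ear_R")
  angles <- seq(1, 20, length.out = 20)
  means <- vapply(seq_along(angles), function(i) {
    po <- simulate_postop(h$mesh, list(center = earc, radius = 50),
                          list(angle_deg = angles[i]), noise_sd = 0,
                          seed = i)
    signed_distance_map(po$mesh, h$mesh)$summary$mean_abs
  }, numeric(1))
  expect_gt(cor(angles, means, method = "spearman"), 0.99)
})
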