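test_that("the distance map of a mesh against itself is exactly zero", {
  h <- test_head()
  dm <- signed_distance_map(h$mesh, h$mesh)
  expect_identical(dm$summary$mean_abs, 0)
  expect_identical(max(abs(dm$per_vertex)), 0)
})

test_that("concentric spheres read the radius gap with the right sign", {
  sph <- auriplan:::uv_sphere(64, 96)
  inner <- trimesh(100 * sph$dirs, sph$faces, name = "r100")
  outer <- trimesh(110 * sph$dirs, sph$faces, name = "r110")
  dm <- signed_distance_map(outer, inner)
  expect_true(all(dm$per_vertex > 0))
  expect_equal(dm$summary$mean_abs, 10, tolerance = 0.01)
  # reversing test and reference flips the sign
  dm_in <- signed_distance_map(inner, outer)
  expect_true(all(dm_in$per_vertex < 0))
  expect_lt(abs(dm_in$summary$mean_abs - 10), 0.1)
  # refinement convergence: the coarse-mesh bias shrinks with resolution
  sph_c <- auriplan:::uv_sphere(16, 24)
  dm_c <- signed_distance_map(trimesh(110 * sph_c$dirs, sph_c$faces),
                              trimesh(100 * sph_c$dirs, sph_c$faces))
  expect_lt(abs(dm$summary$mean_abs - 10), abs(dm_c$summary$mean_abs - 10))
})

test_that("distance maps are invariant under a common rigid motion", {
  h <- test_head()
  earc <- landmark(h$landmarks, "ear_R")
  po <- simulate_postop(h$mesh, list(center = earc, radius = 50),
                        list(angle_deg = 5), noise_sd = 0.2, seed = 2)
  dm <- signed_distance_map(po$mesh, h$mesh)
  T <- iso_compose(translation_isometry(c(30, -12, 44)),
                   rotation_isometry(c(2, 1, -1), 37))
  dm_T <- signed_distance_map(apply_isometry(po$mesh, T),
                              apply_isometry(h$mesh, T))
  expect_lt(max(abs(dm$per_vertex - dm_T$per_vertex)), 1e-9)
})

test_that("distance summaries satisfy their order relations", {
  h <- test_head()
  earc <- landmark(h$landmarks, "ear_R")
  set.seed(4)
  for (i in 1:5) {
    po <- simulate_postop(h$mesh, list(center = earc, radius = 50),
                          list(angle_deg = runif(1, -8, 8),
                               scale = runif(1, 0.9, 1.15)),
                          noise_sd = 0.3, seed = i)
    s <- signed_distance_map(po$mesh, h$mesh)$summary
    expect_lte(s$min, s$mean_signed)
    expect_lte(s$mean_signed, s$max)
    expect_lte(abs(s$mean_signed), s$mean_abs)
    expect_lte(s$mean_abs, max(abs(s$min), abs(s$max)))
    expect_gte(s$sd_abs, 0)
  }
})

test_that("region summaries match the global map and flag empty regions", {
  h <- test_head()
  earc <- landmark(h$landmarks, "ear_R")
  po <- simulate_postop(h$mesh, list(center = earc, radius = 50),
                        list(angle_deg = 6), seed = 3)
  dm <- signed_distance_map(po$mesh, h$mesh)
  rs <- region_summary(dm, po$mesh,
                       list(all = list(center = c(0, 0, 0), radius = 1e6),
                            void = list(center = c(0, 0, 1e4), radius = 5),
                            ear = list(center = earc, radius = 40),
                            nose = list(center = landmark(h$landmarks,
                                                          "nose"),
                                        radius = 25)))
  expect_equal(rs$all, dm$summary)
  expect_null(rs$void)
  expect_identical(attr(rs, "empty_regions"), "void")
  # the perturbation is confined to the ear region
  expect_gt(rs$ear$mean_abs, 20 * rs$nose$mean_abs)
})

test_that("ellipsoid morphometrics recover the analytic extents", {
  sph <- auriplan:::uv_sphere(64, 96)
  ell <- trimesh(cbind(15 * sph$dirs[, 1], 5 * sph$dirs[, 2],
                       30 * sph$dirs[, 3]), sph$faces)
  mo <- ear_morphometrics(ell)
  expect_equal(mo$length, 60, tolerance = 1e-12)
  expect_equal(mo$width, 30, tolerance = 1e-9)
  expect_lt(abs(sum(mo$length_axis * mo$width_axis)), 1e-9)
  expect_gte(mo$length, mo$width)
  # literal minimal-perpendicular reading picks the smallest extent
  mo_min <- ear_morphometrics(ell, width_rule = "min_perpendicular")
  expect_equal(mo_min$width, 10, tolerance = 0.01)
  # rigid invariance
  set.seed(6)
  T <- random_rigid(180, 80)
  mo_T <- ear_morphometrics(apply_isometry(ell, T))
  expect_equal(mo_T$length, mo$length, tolerance = 1e-6)
  expect_equal(mo_T$width, mo$width, tolerance = 1e-6)
})

test_that("caliper length equals the exhaustive pairwise oracle", {
  set.seed(99)
  v <- matrix(rnorm(1500, sd = 20), 500, 3)
  mesh <- trimesh(v, rbind(c(1, 2, 3)))
  mo <- ear_morphometrics(mesh)
  expect_identical(mo$length, oracle_diameter(v))
  expect_error(ear_morphometrics(trimesh(rbind(c(0, 0, 0), c(1, 0, 0),
                                               c(2, 0, 0)),
                                         rbind(c(1, 2, 3)))),
               "degenerate")
})

test_that("comparing the plan against itself reports a null outcome", {
  h <- test_head()
  ev <- compare_to_plan(h$mesh, h$mesh, h$landmarks,
                        evaluation_config(icp_max_iter = 10))
  expect_lt(ev$distance_map$summary$mean_abs, 1e-6)
  expect_lt(abs(ev$morphometrics$length_diff), 1e-6)
  expect_lt(abs(ev$morphometrics$width_diff), 1e-6)
  expect_lt(abs(ev$ear_pose$axial_angle_deg), 0.05)
})

test_that("an axial ear rotation leaves opposite-signed anterior/posterior lobes", {
  h <- test_head()
  earc <- landmark(h$landmarks, "ear_R")
  po <- simulate_postop(h$mesh, list(center = earc, radius = 50),
                        list(axis = c(0, 0, 1), angle_deg = 6),
                        noise_sd = 0.3, seed = 11)
  ev <- compare_to_plan(po$mesh, h$mesh, h$landmarks,
                        evaluation_config(icp_max_iter = 60))
  expect_lt(abs(ev$ear_pose$axial_angle_deg - 6), 0.5)
  reg <- apply_isometry(po$mesh, ev$registration$transform)
  v <- reg$vertices
  d <- ev$distance_map$per_vertex
  in_ear <- sqrt(rowSums(sweep(v, 2, earc)^2)) < 40
  ant <- in_ear & v[, 2] > earc[2] + 4
  post <- in_ear & v[, 2] < earc[2] - 4
  expect_lt(mean(d[ant]), -0.5)
  expect_gt(mean(d[post]), 0.5)
  # away from the ear the map sits at the noise floor
  far <- sqrt(rowSums(sweep(v, 2, earc)^2)) > 60
  expect_lt(mean(abs(d[far])), 3 * 0.3)
})

test_that("evaluation reports serialise to JSON", {
  h <- test_head()
  ev <- compare_to_plan(h$mesh, h$mesh, h$landmarks,
                        evaluation_config(icp_max_iter = 5))
  f <- withr::local_tempfile(fileext = ".json")
  write_evaluation_report(ev, f)
  x <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_identical(x$schema, "auriplan/evaluation/1")
  expect_length(x$registration$matrix, 16)
  expect_true(is.numeric(x$distance_map$mean_abs))
})

test_that("stage failures are labelled with the failing stage", {
  h <- test_head()
  bad_lm <- landmark_set(rbind(somewhere = c(0, 0, 0)))
  expect_error(compare_to_plan(h$mesh, h$mesh, bad_lm), "\\[mask\\]")
})
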