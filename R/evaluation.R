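#' Signed point-to-surface distance map
#'
#' For every vertex of the test mesh, the Euclidean distance to the
#' nearest point on the reference surface (true point-to-triangle foot
#' points, not vertex-to-vertex). The sign is positive when the test
#' vertex lies on the outward-normal side of its nearest reference
#' triangle (e.g. an enlarged ear reads positive against the plan),
#' negative otherwise. The reference model defines the sign. Degenerate
#' reference faces are skipped; equidistant foot points resolve to the
#' lowest face index.
#'
#' Summary statistics follow the outcome-reporting convention: `mean_abs`
#' and `sd_abs` are the mean and population SD of the absolute distances;
#' `mean_signed`, `min` and `max` are over signed values.
#'
#' @param test the [trimesh()] being evaluated (e.g. registered
#'   postoperative scan).
#' @param reference the reference [trimesh()] (e.g. the ideal plan).
#' @return Object of class `distance_map`: `per_vertex` signed distances
#'   (mm), `nearest_face` indices into the reference, `test_name`,
#'   `reference_name`, and `summary` with `mean_abs`, `sd_abs`,
#'   `mean_signed`, `min`, `max`.
#' @export
signed_distance_map <- function(test, reference) {
  stopifnot(inherits(test, "trimesh"), inherits(reference, "trimesh"))
  if (all(reference$degenerate))
    stop("reference mesh has no non-degenerate faces")
  cp <- mesh_closest_points(reference, test$vertices)
  nrm <- face_normals(reference)[cp$face, , drop = FALSE]
  side <- rowSums((test$vertices - cp$foot) * nrm)
  d <- cp$distance * ifelse(side >= 0, 1, -1)
  structure(list(per_vertex = d,
                 nearest_face = cp$face,
                 test_name = test$name,
                 reference_name = reference$name,
                 summary = distance_summary(d)),
            class = "distance_map")
}

distance_summary <- function(d) {
  if (length(d) == 0) return(NULL)
  a <- abs(d)
  list(mean_abs = mean(a),
       sd_abs = sqrt(mean((a - mean(a))^2)),  # population SD
       mean_signed = mean(d),
       min = min(d),
       max = max(d),
       n = length(d))
}

#' @export
print.distance_map <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<distance_map %s vs %s: |d| %.2f +/- %.2f mm, signed [%.2f, %.2f] mm, n=%d>\n",
    x$test_name, x$reference_name, s$mean_abs, s$sd_abs, s$min, s$max, s$n))
  invisible(x)
}

#' Per-region distance summaries
#'
#' Summarises a distance map over landmark-centred spherical regions of
#' the test mesh (cheeks, lips, the ear itself, ...). Vertices may belong
#' to several regions. A region capturing no vertex is flagged with a
#' `NULL` summary rather than raising.
#'
#' @param dmap a [signed_distance_map()] result.
#' @param test the test [trimesh()] the map was computed on.
#' @param regions named list; each element `list(center = 3-vector,
#'   radius = mm)`.
#' @return Named list of summaries (as in [signed_distance_map()]), `NULL`
#'   where empty, with attribute `empty_regions`.
#' @export
region_summary <- function(dmap, test, regions) {
  stopifnot(inherits(dmap, "distance_map"), inherits(test, "trimesh"),
            length(regions) > 0, !is.null(names(regions)))
  out <- vector("list", length(regions))
  names(out) <- names(regions)
  empty <- character(0)
  for (nm in names(regions)) {
    r <- regions[[nm]]
    d2 <- rowSums(sweep(test$vertices, 2, r$center)^2)
    sel <- d2 <= r$radius^2
    if (!any(sel)) {
      out[nm] <- list(NULL)
      empty <- c(empty, nm)
    } else {
      out[[nm]] <- distance_summary(dmap$per_vertex[sel])
    }
  }
  attr(out, "empty_regions") <- empty
  out
}

#' Ear length and width morphometrics
#'
#' Length is the longest dimension of the ear: the maximum pairwise vertex
#' distance (3D caliper diameter; the maximum is attained on convex-hull
#' vertices, and the search is exhaustive over vertices). Width is the
#' extent of vertex projections onto the direction orthogonal to the
#' length axis within the ear's least-squares best-fit plane — the
#' standard auricular width. A literal minimal-perpendicular-extent
#' reading is available via `width_rule = "min_perpendicular"`.
#'
#' @param ear a [trimesh()] (an ear crop).
#' @param width_rule `"in_plane"` (default) or `"min_perpendicular"`.
#' @return Object of class `morphometric_report`: `length`, `width` (mm),
#'   unit `length_axis` and `width_axis` (orthogonal).
#' @export
ear_morphometrics <- function(ear, width_rule = c("in_plane",
                                                  "min_perpendicular")) {
  stopifnot(inherits(ear, "trimesh"))
  width_rule <- match.arg(width_rule)
  v <- ear$vertices
  sv <- svd(sweep(v, 2, colMeans(v)))$d
  if (nrow(v) < 3 || sv[2] <= 1e-9 * max(sv[1], 1))
    stop("degenerate geometry: fewer than 3 non-collinear vertices")
  di <- cp_diameter(v)
  len <- di$diameter
  laxis <- v[di$j, ] - v[di$i, ]
  laxis <- laxis / sqrt(sum(laxis^2))
  if (width_rule == "in_plane") {
    # best-fit plane normal = least-variance direction
    m <- eigen(stats::cov(v), symmetric = TRUE)$vectors[, 3]
    w <- pracma_cross(m, laxis)
    wl <- sqrt(sum(w^2))
    if (wl < 1e-9)
      stop("length axis is normal to the best-fit plane; width undefined")
    w <- w / wl
  } else {
    # search the direction orthogonal to the length axis with the
    # smallest extent
    b1 <- pracma_cross(laxis, c(1, 0, 0))
    if (sqrt(sum(b1^2)) < 1e-6) b1 <- pracma_cross(laxis, c(0, 1, 0))
    b1 <- b1 / sqrt(sum(b1^2))
    b2 <- pracma_cross(laxis, b1)
    th <- seq(0, pi, length.out = 721)[-721]
    ext <- vapply(th, function(a) {
      dir <- cos(a) * b1 + sin(a) * b2
      pr <- v %*% dir
      max(pr) - min(pr)
    }, numeric(1))
    a <- th[which.min(ext)]
    w <- cos(a) * b1 + sin(a) * b2
  }
  pr <- drop(v %*% w)
  width <- max(pr) - min(pr)
  if (width > len) {  # cannot happen for the caliper length, by definition
    width <- len
  }
  structure(list(length = len, width = width,
                 length_axis = laxis, width_axis = w),
            class = "morphometric_report")
}

#' @export
print.morphometric_report <- function(x, ...) {
  cat(sprintf("<morphometrics: length %.2f mm, width %.2f mm>\n",
              x$length, x$width))
  invisible(x)
}

#' Default evaluation configuration
#'
#' Parameters for [compare_to_plan()]: the registration mask (landmark
#' names and sphere radius), ICP settings, the ear crop and the reporting
#' regions.
#'
#' @param mask_names landmark names whose 25 mm spheres form the
#'   registration mask (the mutually stable facial surfaces).
#' @param mask_radius sphere radius, mm.
#' @param ear_center name of the ear-centre landmark (on the plan).
#' @param ear_radius ear crop radius, mm.
#' @param regions optional named list of `list(center=, radius=)` report
#'   regions; defaults to the mask landmarks plus the ear.
#' @param icp_max_iter,icp_tol_mm,icp_reject_percentile ICP settings.
#' @param width_rule passed to [ear_morphometrics()].
#' @return A plain list of settings.
#' @export
evaluation_config <- function(mask_names = c("eye_L", "eye_R", "forehead",
                                             "nose"),
                              mask_radius = 25,
                              ear_center = "ear_R",
                              ear_radius = 40,
                              regions = NULL,
                              icp_max_iter = 100,
                              icp_tol_mm = 1e-4,
                              icp_reject_percentile = 90,
                              width_rule = "in_plane") {
  list(mask_names = mask_names, mask_radius = mask_radius,
       ear_center = ear_center, ear_radius = ear_radius,
       regions = regions, icp_max_iter = icp_max_iter,
       icp_tol_mm = icp_tol_mm,
       icp_reject_percentile = icp_reject_percentile,
       width_rule = width_rule)
}

#' Compare a postoperative scan against the ideal plan
#'
#' The full outcome-evaluation pipeline: region-masked ICP of the
#' postoperative scan onto the plan (masked to the stable facial surfaces
#' so the ear does not drive the alignment), signed distance map of the
#' registered scan against the plan, per-region summaries, ear crops on
#' both models with length/width morphometrics and their differences
#' (final minus specular), and the residual pose of the reconstructed ear
#' relative to the planned one (a second, ear-only ICP), including its
#' rotation about the axial (superior-inferior, +z) axis.
#'
#' @param postop postoperative head [trimesh()] (any frame; it is
#'   registered onto the plan).
#' @param plan ideal-plan head [trimesh()] (defines frame and sign).
#' @param landmarks [landmark_set()] in the plan frame.
#' @param config see [evaluation_config()].
#' @return Object of class `plan_evaluation`: `registration`
#'   ([registration_result()]), `distance_map`, `regions`, `morphometrics`
#'   (`postop`, `plan`, `length_diff`, `width_diff`), `ear_pose`
#'   (`angle_deg`, `axis`, `axial_angle_deg`, `rms`), each stage labelled
#'   on error.
#' @export
compare_to_plan <- function(postop, plan, landmarks,
                            config = evaluation_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  mask_centers <- stage("mask", {
    missing <- setdiff(config$mask_names, rownames(landmarks$points))
    if (length(missing) > 0)
      stop(sprintf("landmarks missing: %s", paste(missing, collapse = ", ")))
    landmarks$points[config$mask_names, , drop = FALSE]
  })
  reg <- stage("registration",
    icp(postop, plan,
        mask = list(centers = mask_centers, radius = config$mask_radius),
        max_iter = config$icp_max_iter, tol_mm = config$icp_tol_mm,
        reject_percentile = config$icp_reject_percentile))
  registered <- apply_isometry(postop, reg$transform)
  dmap <- stage("distance_map", signed_distance_map(registered, plan))
  ear_c <- stage("ear_crop", landmark(landmarks, config$ear_center))
  regions <- config$regions
  if (is.null(regions)) {
    regions <- lapply(seq_len(nrow(mask_centers)), function(i)
      list(center = mask_centers[i, ], radius = config$mask_radius))
    names(regions) <- config$mask_names
    regions$ear <- list(center = ear_c, radius = config$ear_radius)
  }
  rsum <- stage("region_summary", region_summary(dmap, registered, regions))
  ear_post <- stage("ear_crop",
                    crop_region(registered, ear_c, config$ear_radius))
  ear_plan <- stage("ear_crop", crop_region(plan, ear_c, config$ear_radius))
  morph <- stage("morphometrics", {
    mp <- ear_morphometrics(ear_post, config$width_rule)
    ml <- ear_morphometrics(ear_plan, config$width_rule)
    list(postop = mp, plan = ml,
         length_diff = mp$length - ml$length,
         width_diff = mp$width - ml$width)
  })
  ear_pose <- stage("ear_pose", {
    fit <- icp(ear_plan, ear_post, max_iter = 60, tol_mm = 1e-5,
               reject_percentile = 95)
    R <- fit$transform[1:3, 1:3]
    aa <- R_to_axis_angle(R)
    ang <- sqrt(sum(aa^2)) * 180 / pi
    list(angle_deg = ang,
         axis = if (ang > 0) aa / sqrt(sum(aa^2)) else c(0, 0, 1),
         axial_angle_deg = atan2(R[2, 1] - R[1, 2],
                                 R[1, 1] + R[2, 2]) * 180 / pi,
         rms = fit$rms)
  })
  structure(list(registration = reg, distance_map = dmap, regions = rsum,
                 morphometrics = morph, ear_pose = ear_pose,
                 config = config),
            class = "plan_evaluation")
}

#' @export
print.plan_evaluation <- function(x, ...) {
  s <- x$distance_map$summary
  cat(sprintf("<plan_evaluation: |d| %.2f +/- %.2f mm (min %.2f, max %.2f)>\n",
              s$mean_abs, s$sd_abs, s$min, s$max))
  cat(sprintf("  ear length diff %+.2f mm, width diff %+.2f mm, axial rotation %+.2f deg\n",
              x$morphometrics$length_diff, x$morphometrics$width_diff,
              x$ear_pose$axial_angle_deg))
  invisible(x)
}

#' Write an evaluation report to JSON
#'
#' Serialises a [compare_to_plan()] result (registration transform,
#' distance-map summary, region summaries, morphometrics, ear pose) to a
#' schema-versioned JSON file.
#'
#' @param evaluation a `plan_evaluation`.
#' @param path output path.
#' @export
write_evaluation_report <- function(evaluation, path) {
  stopifnot(inherits(evaluation, "plan_evaluation"))
  x <- list(
    schema = "auriplan/evaluation/1",
    registration = list(
      matrix = as.numeric(t(unclass(evaluation$registration$transform))),
      rms_mm = evaluation$registration$rms,
      iterations = evaluation$registration$iterations,
      converged = evaluation$registration$converged),
    distance_map = evaluation$distance_map$summary,
    regions = evaluation$regions,
    morphometrics = list(
      postop = evaluation$morphometrics$postop[c("length", "width")],
      plan = evaluation$morphometrics$plan[c("length", "width")],
      length_diff = evaluation$morphometrics$length_diff,
      width_diff = evaluation$morphometrics$width_diff),
    ear_pose = evaluation$ear_pose)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
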