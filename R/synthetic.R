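# run expr with a temporary RNG state so generators are deterministic
# without disturbing the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
  })
  expr
}

#' Specification for a synthetic head
#'
#' Parameters of the deterministic head generator. Defaults describe a
#' child-sized head in the RAS frame, millimetres: ellipsoid semi-axes
#' (right-left 70, antero-posterior 85, supero-inferior 105 mm) and a
#' schematic parametric ear (elliptical base pad plus a helix-like ridge)
#' of height 55, width 30 mm, ridge thickness 6 mm, protruding 12 mm from
#' the head — the scale of a paediatric auricle. The right ear is the
#' exact mirror of the left through the x = 0 midsagittal plane unless an
#' `asymmetry` perturbation (scale, rotation about the axial axis,
#' translation) is requested.
#'
#' @param seed integer; fixed seed gives byte-identical meshes.
#' @param head_radii semi-axes `c(x, y, z)` in mm.
#' @param ear_params list with `height`, `width`, `thickness`,
#'   `protrusion` (mm).
#' @param asymmetry `NULL`, or list with any of `scale`, `rotation_deg`
#'   (about the axial axis), `translation` (3-vector mm) applied to the
#'   right ear region.
#' @param noise_sd isotropic Gaussian vertex noise SD (mm, default 0).
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L,
                       head_radii = c(70, 85, 105),
                       ear_params = list(height = 55, width = 30,
                                         thickness = 6, protrusion = 12),
                       asymmetry = NULL,
                       noise_sd = 0) {
  stopifnot(all(head_radii > 0),
            all(unlist(ear_params[c("height", "width", "thickness",
                                    "protrusion")]) > 0),
            noise_sd >= 0)
  structure(list(seed = as.integer(seed), head_radii = head_radii,
                 ear_params = ear_params, asymmetry = asymmetry,
                 noise_sd = noise_sd),
            class = "synth_spec")
}

# unit directions and faces of a closed UV sphere whose vertex set is
# exactly mirror-symmetric in x (poles on the z axis; requires nlon
# divisible by 4 so the ear directions (+-1,0,0) fall on vertices)
uv_sphere <- function(nlat, nlon) {
  stopifnot(nlat >= 3, nlon >= 8, nlon %% 4 == 0)
  th <- pi * seq_len(nlat - 1) / nlat
  ph <- 2 * pi * (seq_len(nlon) - 1) / nlon
  g <- expand.grid(ph = ph, th = th)
  dirs <- rbind(c(0, 0, 1),
                cbind(sin(g$th) * sin(g$ph), sin(g$th) * cos(g$ph),
                      cos(g$th)),
                c(0, 0, -1))
  idx <- function(i, j)
    as.integer(1L + (i - 1L) * nlon + ((j - 1L) %% nlon) + 1L)
  top <- t(vapply(seq_len(nlon), function(j)
    c(1L, idx(1L, j + 1L), idx(1L, j)), integer(3)))
  bot_v <- nrow(dirs)
  bottom <- t(vapply(seq_len(nlon), function(j)
    c(bot_v, idx(nlat - 1L, j), idx(nlat - 1L, j + 1L)), integer(3)))
  quads <- list()
  for (i in seq_len(nlat - 2L)) {
    a <- vapply(seq_len(nlon), function(j) idx(i, j), integer(1))
    b <- vapply(seq_len(nlon), function(j) idx(i, j + 1L), integer(1))
    c_ <- vapply(seq_len(nlon), function(j) idx(i + 1L, j + 1L), integer(1))
    d <- vapply(seq_len(nlon), function(j) idx(i + 1L, j), integer(1))
    quads[[i]] <- rbind(cbind(a, b, c_), cbind(a, c_, d))
  }
  list(dirs = dirs, faces = rbind(top, do.call(rbind, quads), bottom))
}

# radial displacement field of the head features at unit directions u;
# which_ears selects the sides that carry an ear
head_displacement <- function(u, spec, which_ears = c("left", "right")) {
  r <- spec$head_radii
  ep <- spec$ear_params
  p0y <- r[2] * u[, 2]
  p0z <- r[3] * u[, 3]
  disp <- numeric(nrow(u))
  for (side in which_ears) {
    sgn <- if (side == "left") -1 else 1
    on_side <- sgn * u[, 1] > 0
    rho <- sqrt((p0y / (ep$width / 2))^2 + (p0z / (ep$height / 2))^2)
    pad <- ifelse(rho < 1, 0.5 * (1 + cos(pi * pmin(rho, 1))), 0)
    ridge <- exp(-((rho - 0.75) / 0.15)^2)
    disp <- disp + on_side * (ep$protrusion * pad + ep$thickness * ridge *
                                (rho < 1.2))
  }
  ang_to <- function(center) {
    c0 <- center / sqrt(sum(center^2))
    acos(pmin(1, pmax(-1, u %*% c0)))
  }
  cosramp <- function(ang, radius)
    ifelse(ang < radius, 0.5 * (1 + cos(pi * ang / radius)), 0)
  disp <- disp + 14 * cosramp(ang_to(c(0, 1, 0)), 0.35)          # nose
  disp <- disp + 6 * cosramp(ang_to(c(0.35, 0.85, 0.30)), 0.25)  # brows
  disp <- disp + 6 * cosramp(ang_to(c(-0.35, 0.85, 0.30)), 0.25)
  drop(disp)
}

synth_landmark_dirs <- function() {
  nrm <- function(x) x / sqrt(sum(x^2))
  list(eye_L = nrm(c(-0.30, 0.90, 0.12)),
       eye_R = nrm(c(0.30, 0.90, 0.12)),
       nose = c(0, 1, 0),
       forehead = nrm(c(0, 0.55, 0.83)),
       ear_L = c(-1, 0, 0),
       ear_R = c(1, 0, 0))
}

synth_surface_point <- function(dir, spec, which_ears) {
  u <- matrix(dir, 1, 3)
  base <- c(spec$head_radii[1] * dir[1], spec$head_radii[2] * dir[2],
            spec$head_radii[3] * dir[3])
  base + head_displacement(u, spec, which_ears) * dir
}

# cosine-ramp blend weight: 1 inside ramp_start*radius, 0 outside radius
blend_weight <- function(d, radius, ramp_start = 0.8) {
  r0 <- ramp_start * radius
  w <- numeric(length(d))
  w[d <= r0] <- 1
  ramp <- d > r0 & d < radius
  w[ramp] <- 0.5 * (1 + cos(pi * (d[ramp] - r0) / (radius - r0)))
  w
}

# apply T to vertices near center with smooth falloff
blend_transform_region <- function(vertices, center, radius, T,
                                   ramp_start = 0.8) {
  d <- sqrt(rowSums(sweep(vertices, 2, center)^2))
  w <- blend_weight(d, radius, ramp_start)
  moved <- iso_apply(T, vertices)
  vertices + w * (moved - vertices)
}

scaling_about <- function(scale, center) {
  # not an isometry; returned as a plain function
  function(v) sweep(sweep(v, 2, center) * scale, 2, center, "+")
}

#' Generate a synthetic head with parametric ears
#'
#' Deterministic stand-in for a patient head scan: a closed ellipsoidal
#' head with nose and brow features (so masked registration has
#' structure), a schematic parametric ear on each side (elliptical base
#' pad plus helix-like ridge), the right ear an exact mirror of the left
#' through the known x = 0 midsagittal plane, then the optional asymmetry
#' perturbation and vertex noise. Landmarks are emitted for both eyes,
#' forehead, nose and both ear centres.
#'
#' @param spec a [synth_spec()].
#' @param resolution `c(nlat, nlon)` sphere tessellation (default
#'   `c(64, 96)`, ~6000 vertices; `nlon` must be divisible by 4).
#' @return List with `mesh` ([trimesh()]), `landmarks`
#'   ([landmark_set()]) and `ground_truth` (list: `sagittal_plane`,
#'   `landmarks`, `ear_region`, `perturbation_applied`, plus the `spec`
#'   and `resolution` needed to regenerate).
#' @export
make_head <- function(spec = synth_spec(), resolution = c(64, 96)) {
  stopifnot(inherits(spec, "synth_spec"))
  sph <- uv_sphere(resolution[1], resolution[2])
  u <- sph$dirs
  base <- cbind(spec$head_radii[1] * u[, 1], spec$head_radii[2] * u[, 2],
                spec$head_radii[3] * u[, 3])
  v <- base + head_displacement(u, spec) * u
  lm_dirs <- synth_landmark_dirs()
  lm_pts <- t(vapply(lm_dirs, synth_surface_point, numeric(3),
                     spec = spec, which_ears = c("left", "right")))
  lms <- landmark_set(lm_pts, frame = "RAS")
  ear_radius <- 0.8 * spec$ear_params$height
  perturb <- NULL
  if (!is.null(spec$asymmetry)) {
    a <- spec$asymmetry
    ctr <- landmark(lms, "ear_R")
    scale <- a$scale %||% 1
    rot <- a$rotation_deg %||% 0
    tra <- a$translation %||% c(0, 0, 0)
    T <- iso_compose(translation_isometry(tra),
                     rotation_isometry(c(0, 0, 1), rot, center = ctr))
    d <- sqrt(rowSums(sweep(v, 2, ctr)^2))
    w <- blend_weight(d, ear_radius)
    target <- iso_apply(T, scaling_about(scale, ctr)(v))
    v <- v + w * (target - v)
    perturb <- list(kind = "asymmetry", center = ctr, radius = ear_radius,
                    scale = scale, rotation_deg = rot, translation = tra,
                    axis = c(0, 0, 1))
  }
  if (spec$noise_sd > 0)
    v <- v + with_seed(spec$seed,
                       matrix(rnorm(length(v), sd = spec$noise_sd),
                              ncol = 3))
  mesh <- trimesh(v, sph$faces, name = "synthetic_head")
  list(mesh = mesh, landmarks = lms,
       ground_truth = list(
         sagittal_plane = plane(c(1, 0, 0), 0),
         landmarks = lms,
         ear_region = list(center_L = landmark(lms, "ear_L"),
                           center_R = landmark(lms, "ear_R"),
                           radius = ear_radius),
         perturbation_applied = perturb,
         spec = spec, resolution = resolution))
}

#' Emulate microtia/anotia by removing one ear
#'
#' Regenerates the head with the chosen side's ear displacement
#' suppressed, i.e. the ear replaced by the smooth bare head surface. The
#' mesh stays closed and every vertex outside the ear footprint —
#' including the entire healthy ear — is bit-identical to the input head.
#'
#' @param head the head [trimesh()] from [make_head()].
#' @param side `"left"` or `"right"`.
#' @param ground the `ground_truth` from the same [make_head()] call.
#' @return The affected-head [trimesh()].
#' @export
make_microtia_case <- function(head, side = c("left", "right"), ground) {
  side <- match.arg(side)
  spec <- ground$spec
  if (!is.null(spec$asymmetry) || spec$noise_sd > 0)
    stop("microtia emulation expects a symmetric noise-free head")
  sph <- uv_sphere(ground$resolution[1], ground$resolution[2])
  u <- sph$dirs
  base <- cbind(spec$head_radii[1] * u[, 1], spec$head_radii[2] * u[, 2],
                spec$head_radii[3] * u[, 3])
  keep <- setdiff(c("left", "right"), side)
  v <- base + head_displacement(u, spec, which_ears = keep) * u
  if (max(abs(dim(v) - dim(head$vertices))) != 0)
    stop("head does not match its ground truth resolution")
  trimesh(v, sph$faces, name = sprintf("synthetic_head_no_%s_ear", side))
}

#' Simulate a postoperative scan from the plan
#'
#' Applies a known rigid-plus-scale perturbation to the ear region of the
#' plan head — rotation about a given axis through the ear-region
#' centroid (clinically, residual rotation about the axial axis),
#' translation, uniform inflation — blended smoothly to identity over the
#' outer 20 percent of the region radius (so crease artefacts do not
#' dominate the distance maps), then adds independent Gaussian vertex
#' noise everywhere.
#'
#' @param plan_head the plan [trimesh()].
#' @param ear_region list `(center = 3-vector, radius = mm)`.
#' @param perturbation list with `axis` (default axial, `c(0,0,1)`),
#'   `angle_deg` (|angle| <= 30), `translation` (mm), `scale`
#'   (within 0.8 - 1.3).
#' @param noise_sd Gaussian vertex noise SD (mm).
#' @param seed integer noise seed.
#' @return List with `mesh` and `ground_truth` (the perturbation, its
#'   centre/axis and the noise level).
#' @export
simulate_postop <- function(plan_head, ear_region,
                            perturbation = list(axis = c(0, 0, 1),
                                                angle_deg = 0,
                                                translation = c(0, 0, 0),
                                                scale = 1),
                            noise_sd = 0, seed = 1L) {
  stopifnot(inherits(plan_head, "trimesh"))
  axis <- perturbation$axis %||% c(0, 0, 1)
  angle <- perturbation$angle_deg %||% 0
  tra <- perturbation$translation %||% c(0, 0, 0)
  scale <- perturbation$scale %||% 1
  if (abs(angle) > 30) stop("perturbation angle must be within +-30 degrees")
  if (scale < 0.8 || scale > 1.3)
    stop("perturbation scale must be within [0.8, 1.3]")
  v <- plan_head$vertices
  ctr <- ear_region$center
  radius <- ear_region$radius
  d <- sqrt(rowSums(sweep(v, 2, ctr)^2))
  sel <- d <= radius
  centroid <- colMeans(v[sel, , drop = FALSE])
  T <- iso_compose(translation_isometry(tra),
                   rotation_isometry(axis, angle, center = centroid))
  target <- iso_apply(T, scaling_about(scale, centroid)(v))
  w <- blend_weight(d, radius)
  v2 <- v + w * (target - v)
  if (noise_sd > 0)
    v2 <- v2 + with_seed(seed, matrix(rnorm(length(v2), sd = noise_sd),
                                      ncol = 3))
  list(mesh = trimesh(v2, plan_head$faces, name = "synthetic_postop"),
       ground_truth = list(center = ctr, radius = radius,
                           centroid = centroid,
                           rotation = list(axis = axis / sqrt(sum(axis^2)),
                                           angle_deg = angle),
                           translation = tra, scale = scale,
                           noise_sd = noise_sd, seed = seed))
}

#' Fabricate cube-marker observations for a known pose
#'
#' Stands in for the pattern detector: projects the corners of every
#' visible cube face (back-face culling via the face normal against the
#' view ray; a face also needs all four corners in front of the camera
#' and inside the image) under the true pose and adds Gaussian pixel
#' noise.
#'
#' @param camera a [camera_model()].
#' @param marker a [marker_model()].
#' @param true_pose rigid [isometry()], camera-from-marker.
#' @param pixel_noise_sd pixel noise SD (default 0).
#' @param seed noise seed.
#' @return List with `observations` (data.frame `face`, `corner`, `u`,
#'   `v`) and `ground_truth` (`pose`, `visible_faces`, `pixel_noise_sd`,
#'   `seed`).
#' @export
synth_marker_scene <- function(camera, marker, true_pose,
                               pixel_noise_sd = 0, seed = 1L) {
  stopifnot(inherits(camera, "camera_model"),
            inherits(marker, "marker_model"),
            inherits(true_pose, "isometry"))
  obs <- list()
  visible <- character(0)
  for (nm in names(marker$faces)) {
    corners <- marker$faces[[nm]]
    cam_pts <- iso_apply(true_pose, corners)
    if (any(cam_pts[, 3] <= 1e-6)) next
    ctr <- colMeans(cam_pts)
    e1 <- cam_pts[2, ] - cam_pts[1, ]
    e2 <- cam_pts[4, ] - cam_pts[1, ]
    n <- pracma_cross(e1, e2)  # outward normal (corners CCW from outside)
    if (sum(n * ctr) >= 0) next  # back-facing
    uv <- project_points(camera, iso_identity(), cam_pts)
    inside <- uv[, 1] >= 0 & uv[, 1] <= camera$image_size[1] &
      uv[, 2] >= 0 & uv[, 2] <= camera$image_size[2]
    if (!all(inside)) next
    visible <- c(visible, nm)
    obs[[nm]] <- data.frame(face = nm, corner = 1:4,
                            u = uv[, 1], v = uv[, 2],
                            stringsAsFactors = FALSE)
  }
  if (length(visible) == 0)
    stop("no marker face is visible from the given pose")
  observations <- do.call(rbind, obs)
  rownames(observations) <- NULL
  if (pixel_noise_sd > 0) {
    noise <- with_seed(seed, matrix(rnorm(2 * nrow(observations),
                                          sd = pixel_noise_sd), ncol = 2))
    observations$u <- observations$u + noise[, 1]
    observations$v <- observations$v + noise[, 2]
  }
  list(observations = observations,
       ground_truth = list(pose = true_pose, visible_faces = visible,
                           pixel_noise_sd = pixel_noise_sd, seed = seed))
}
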