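#' Pinhole camera model
#'
#' Abstraction of the tablet camera: focal lengths and principal point in
#' pixels, image size, and optional radial distortion `(k1, k2)` applied
#' to normalised coordinates.
#'
#' @param fx,fy focal lengths (px, > 0).
#' @param cx,cy principal point (px, inside the image).
#' @param image_size `c(width, height)` in px.
#' @param k1,k2 radial distortion coefficients (default 0).
#' @return Object of class `camera_model`.
#' @export
camera_model <- function(fx, fy, cx, cy, image_size, k1 = 0, k2 = 0) {
  stopifnot(fx > 0, fy > 0, length(image_size) == 2)
  if (cx < 0 || cx > image_size[1] || cy < 0 || cy > image_size[2])
    stop("principal point must lie inside the image")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 image_size = as.numeric(image_size), k1 = k1, k2 = k2),
            class = "camera_model")
}

#' @rdname camera_model
#' @param path JSON file with fields `fx, fy, cx, cy, image_size[, k1, k2]`.
#' @export
read_camera <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  camera_model(x$fx, x$fy, x$cx, x$cy, as.numeric(x$image_size),
               x$k1 %||% 0, x$k2 %||% 0)
}

#' Cube fiducial marker model
#'
#' The patterned reference cube that anchors the guidance chain. Each of
#' the six faces carries four corner points in the marker frame (origin at
#' the cube centre). Corners are ordered counter-clockwise viewed from
#' outside, starting at the face's `+e1+e2` corner for the face-local
#' right-handed basis `(e1, e2, n)`.
#'
#' @param side cube edge length in mm (default 30).
#' @return Object of class `marker_model` with `side` and `faces`, a named
#'   list (`x+`, `x-`, `y+`, `y-`, `z+`, `z-`) of 4 x 3 corner matrices.
#' @export
marker_model <- function(side = 30) {
  stopifnot(side > 0)
  h <- side / 2
  ax <- list(`x+` = list(n = c(1, 0, 0), e1 = c(0, 1, 0), e2 = c(0, 0, 1)),
             `x-` = list(n = c(-1, 0, 0), e1 = c(0, 0, 1), e2 = c(0, 1, 0)),
             `y+` = list(n = c(0, 1, 0), e1 = c(0, 0, 1), e2 = c(1, 0, 0)),
             `y-` = list(n = c(0, -1, 0), e1 = c(1, 0, 0), e2 = c(0, 0, 1)),
             `z+` = list(n = c(0, 0, 1), e1 = c(1, 0, 0), e2 = c(0, 1, 0)),
             `z-` = list(n = c(0, 0, -1), e1 = c(1, 0, 0), e2 = c(0, -1, 0)))
  signs <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))  # CCW from outside
  faces <- lapply(ax, function(a) {
    ctr <- h * a$n
    t(vapply(seq_len(4), function(k)
      ctr + h * signs[k, 1] * a$e1 + h * signs[k, 2] * a$e2, numeric(3)))
  })
  structure(list(side = side, faces = faces), class = "marker_model")
}

#' @rdname marker_model
#' @param path JSON file with field `side`.
#' @export
read_marker <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  marker_model(x$side %||% 30)
}

marker_corner <- function(marker, face, corner) {
  marker$faces[[face]][corner, ]
}

#' Project 3D points through a pinhole camera
#'
#' Standard pinhole projection with optional radial distortion:
#' `u = fx * xd + cx`, `v = fy * yd + cy` where `(xd, yd)` are the
#' distorted normalised coordinates.
#'
#' @param camera a [camera_model()].
#' @param T_cam_from_obj [isometry()] mapping object coordinates into the
#'   camera frame (+z forward).
#' @param points n x 3 matrix or 3-vector, object frame (mm).
#' @return n x 2 matrix of pixel coordinates.
#' @export
project_points <- function(camera, T_cam_from_obj, points) {
  p <- iso_apply(T_cam_from_obj, points)
  if (is.null(dim(p))) p <- matrix(p, 1, 3)
  behind <- which(p[, 3] <= 1e-9)
  if (length(behind) > 0)
    stop(sprintf("points at or behind the camera plane: %s",
                 paste(behind, collapse = ", ")))
  xn <- p[, 1] / p[, 3]
  yn <- p[, 2] / p[, 3]
  r2 <- xn^2 + yn^2
  f <- 1 + camera$k1 * r2 + camera$k2 * r2^2
  cbind(camera$fx * xn * f + camera$cx,
        camera$fy * yn * f + camera$cy)
}

# undistort normalised coordinates by fixed-point iteration
undistort_normalised <- function(camera, xn, yn) {
  if (camera$k1 == 0 && camera$k2 == 0) return(cbind(xn, yn))
  xu <- xn; yu <- yn
  for (i in 1:20) {
    r2 <- xu^2 + yu^2
    f <- 1 + camera$k1 * r2 + camera$k2 * r2^2
    xu <- xn / f
    yu <- yn / f
  }
  cbind(xu, yu)
}

axis_angle_to_R <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  a <- w / th
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

R_to_axis_angle <- function(R) {
  c_ <- (sum(diag(R)) - 1) / 2
  th <- acos(min(1, max(-1, c_)))
  if (th < 1e-12) return(c(0, 0, 0))
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  len <- sqrt(sum(ax^2))
  if (len < 1e-12) {  # th ~ pi
    M <- (R + diag(3)) / 2
    k <- which.max(diag(M))
    ax <- M[, k] / sqrt(M[k, k])
    return(th * ax)
  }
  th * ax / len
}

pose_params_to_iso <- function(par) {
  m <- diag(4)
  m[1:3, 1:3] <- axis_angle_to_R(par[1:3])
  m[1:3, 4] <- par[4:6]
  isometry(m, "rigid")
}

reproj_residuals <- function(par, camera, P, uv) {
  T <- pose_params_to_iso(par)
  pc <- iso_apply(T, P)
  if (is.null(dim(pc))) pc <- matrix(pc, 1, 3)
  if (any(pc[, 3] <= 1e-9)) return(NULL)
  xn <- pc[, 1] / pc[, 3]
  yn <- pc[, 2] / pc[, 3]
  r2 <- xn^2 + yn^2
  f <- 1 + camera$k1 * r2 + camera$k2 * r2^2
  pred <- cbind(camera$fx * xn * f + camera$cx,
                camera$fy * yn * f + camera$cy)
  as.vector(pred - uv)
}

# planar homography pose for one cube face (DLT + orthonormalisation)
homography_pose <- function(camera, P3, uv) {
  # face-local 2D frame
  ctr <- colMeans(P3)
  B <- svd(sweep(P3, 2, ctr))$v[, 1:2]
  XY <- sweep(P3, 2, ctr) %*% B
  norm_uv <- undistort_normalised(camera,
                                  (uv[, 1] - camera$cx) / camera$fx,
                                  (uv[, 2] - camera$cy) / camera$fy)
  n <- nrow(XY)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    X <- c(XY[i, ], 1)
    A[2 * i - 1, ] <- c(-X, 0, 0, 0, norm_uv[i, 1] * X)
    A[2 * i, ] <- c(0, 0, 0, -X, norm_uv[i, 2] * X)
  }
  h <- eigen(crossprod(A), symmetric = TRUE)$vectors[, 9]
  H <- matrix(h, 3, 3, byrow = TRUE)
  s <- sqrt(sum(H[, 1]^2) * sum(H[, 2]^2))^(1 / 2)
  H <- H / s
  if (H[3, 3] < 0) H <- -H
  r1 <- H[, 1]; r2 <- H[, 2]; t <- H[, 3]
  R0 <- cbind(r1, r2, pracma_cross(r1, r2))
  sv <- svd(R0)
  R <- sv$u %*% diag(c(1, 1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
  # camera pose of the face-local frame -> marker frame
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- t
  T_cam_from_face <- isometry(m, "rigid")
  mf <- diag(4)
  mf[1:3, 1:3] <- cbind(B, pracma_cross(B[, 1], B[, 2]))
  mf[1:3, 4] <- ctr
  T_marker_from_face <- isometry(mf, "rigid")
  iso_compose(T_cam_from_face, iso_invert(T_marker_from_face))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Estimate the cube-marker pose from pixel observations
#'
#' Solves the marker pose (camera-from-marker) that minimises the pixel
#' reprojection error of observed cube corners, by damped least squares
#' (Gauss-Newton with a Levenberg fallback: lambda starts at 1e-3, x10 on
#' a failed step, /10 on success, at most 100 iterations, convergence at
#' an RMS change below 1e-10 px). When no initial pose is supplied, a
#' planar-homography pose on the most-observed face initialises the
#' refinement. Marker detection itself (the pattern recogniser's job) is
#' out of scope: observations arrive as `(face, corner, u, v)` records.
#'
#' @param observations data.frame with columns `face` (one of `x+`, `x-`,
#'   `y+`, `y-`, `z+`, `z-`), `corner` (1-4) and pixel coordinates
#'   `u`, `v`.
#' @param marker a [marker_model()].
#' @param camera a [camera_model()].
#' @param init optional initial [isometry()].
#' @return A [registration_result()]; `transform` is T_cam_from_marker,
#'   `rms` the reprojection RMS in px.
#' @export
estimate_marker_pose <- function(observations, marker, camera, init = NULL) {
  obs <- as.data.frame(observations)
  stopifnot(all(c("face", "corner", "u", "v") %in% names(obs)))
  if (nrow(obs) < 4)
    stop("insufficient observations: need at least 4 corners")
  P <- t(mapply(function(f, c_) marker_corner(marker, f, c_),
                as.character(obs$face), obs$corner))
  uv <- cbind(obs$u, obs$v)
  sv <- svd(sweep(P, 2, colMeans(P)))$d
  if (sv[2] <= 1e-9 * max(sv[1], 1))
    stop("observed corners are collinear")
  if (is.null(init)) {
    counts <- table(as.character(obs$face))
    best_face <- names(counts)[which.max(counts)]
    sel <- which(as.character(obs$face) == best_face)
    if (length(sel) >= 4) {
      init <- homography_pose(camera, P[sel, , drop = FALSE],
                              uv[sel, , drop = FALSE])
    } else {
      # rough scale-from-spread initialisation
      spread <- max(stats::dist(uv))
      z0 <- camera$fx * marker$side / max(spread, 1)
      init <- translation_isometry(c(0, 0, z0))
    }
  }
  par <- c(R_to_axis_angle(init[1:3, 1:3]), init[1:3, 4])
  r <- reproj_residuals(par, camera, P, uv)
  if (is.null(r)) {
    # noisy homographies occasionally decompose to a pose behind the
    # camera; restart from a frontal scale-from-spread guess
    spread <- max(stats::dist(uv))
    par <- c(0, 0, 0, 0, 0, camera$fx * marker$side / max(spread, 1))
    r <- reproj_residuals(par, camera, P, uv)
    if (is.null(r)) stop("initial pose places corners behind the camera")
  }
  rms <- sqrt(mean(r^2))
  lambda <- 1e-3
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(100)) {
    iterations <- it
    # numeric Jacobian
    J <- matrix(0, length(r), 6)
    for (k in 1:6) {
      h <- max(1e-7, 1e-7 * abs(par[k]))
      pk <- par; pk[k] <- pk[k] + h
      rk <- reproj_residuals(pk, camera, P, uv)
      if (is.null(rk)) rk <- r
      J[, k] <- (rk - r) / h
    }
    JtJ <- crossprod(J)
    g <- crossprod(J, r)
    step_ok <- FALSE
    for (tries in 1:12) {
      delta <- tryCatch(solve(JtJ + lambda * diag(diag(JtJ)) +
                                1e-12 * diag(6), -g),
                        error = function(e) NULL)
      if (!is.null(delta)) {
        new_par <- par + as.vector(delta)
        new_r <- reproj_residuals(new_par, camera, P, uv)
        if (!is.null(new_r) && sqrt(mean(new_r^2)) <= rms) {
          drms <- rms - sqrt(mean(new_r^2))
          par <- new_par
          r <- new_r
          rms <- sqrt(mean(r^2))
          lambda <- max(lambda / 10, 1e-12)
          step_ok <- TRUE
          if (drms < 1e-10) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!step_ok) {
      converged <- TRUE  # no further descent possible
      break
    }
    if (converged) break
  }
  if (!converged && !is.finite(rms))
    stop(sprintf("pose refinement diverged (last rms %.3g px)", rms))
  registration_result(pose_params_to_iso(par), rms,
                      iterations = max(iterations, 1L),
                      converged = converged,
                      correspondences_used = nrow(obs),
                      rms_history = rms)
}

#' Splint-anchored guidance transform chain
#'
#' Carries the three fixed links of the AR chain: marker-from-splint (from
#' the CAD design of the splint adaptor), splint-from-head (from plan
#' registration) and head-from-earplan (pose of the specular ear in the
#' head frame, identity by default).
#'
#' @param T_marker_from_splint,T_splint_from_head,T_head_from_earplan
#'   rigid [isometry()] objects.
#' @return Object of class `guidance_chain`.
#' @export
guidance_chain <- function(T_marker_from_splint = iso_identity(),
                           T_splint_from_head = iso_identity(),
                           T_head_from_earplan = iso_identity()) {
  chain <- list(T_marker_from_splint = T_marker_from_splint,
                T_splint_from_head = T_splint_from_head,
                T_head_from_earplan = T_head_from_earplan)
  for (T in chain)
    stopifnot(inherits(T, "isometry"), attr(T, "kind") == "rigid")
  structure(chain, class = "guidance_chain")
}

#' Compose the guidance chain into a camera-frame ear pose
#'
#' `T_cam_from_earplan = T_cam_from_marker o T_marker_from_splint o
#' T_splint_from_head o T_head_from_earplan`: the pose at which the
#' virtual ear is rendered once the marker is detected.
#'
#' @param chain a [guidance_chain()].
#' @param T_cam_from_marker rigid [isometry()] from marker pose
#'   estimation.
#' @return Rigid [isometry()] placing plan-frame ear coordinates in the
#'   camera frame.
#' @export
compose_guidance <- function(chain, T_cam_from_marker) {
  stopifnot(inherits(chain, "guidance_chain"))
  iso_compose(T_cam_from_marker,
              iso_compose(chain$T_marker_from_splint,
                          iso_compose(chain$T_splint_from_head,
                                      chain$T_head_from_earplan)))
}

#' Mean 2D contour distance between two projected silhouettes
#'
#' Visual-verification metric: the mesh is projected under both poses, the
#' 2D convex-hull contour of each projection is resampled densely by arc
#' length, and the symmetric mean nearest-point distance between the two
#' contours is returned (0 iff the silhouettes coincide, up to contour
#' sampling).
#'
#' @param mesh a [trimesh()].
#' @param camera a [camera_model()].
#' @param pose_a,pose_b rigid [isometry()] camera-from-object poses.
#' @param n_samples contour resampling density (default 512).
#' @return Mean contour distance in px.
#' @export
silhouette_overlay_error <- function(mesh, camera, pose_a, pose_b,
                                     n_samples = 512) {
  ca <- silhouette_contour(mesh, camera, pose_a, n_samples)
  cb <- silhouette_contour(mesh, camera, pose_b, n_samples)
  (mean_nearest_to_polygon(ca, cb) + mean_nearest_to_polygon(cb, ca)) / 2
}

silhouette_contour <- function(mesh, camera, pose, n_samples) {
  uv <- project_points(camera, pose, mesh$vertices)
  hull <- uv[chull(uv), , drop = FALSE]
  resample_polygon(hull, n_samples)
}

resample_polygon <- function(poly, n) {
  closed <- rbind(poly, poly[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- seq(0, total, length.out = n + 1)[-(n + 1)]
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i[i > nrow(poly)] <- nrow(poly)
  frac <- (s - cum[i]) / pmax(seg[i], 1e-300)
  closed[i, , drop = FALSE] +
    (closed[i + 1, , drop = FALSE] - closed[i, , drop = FALSE]) * frac
}

mean_nearest_to_polygon <- function(pts, poly) {
  closed <- rbind(poly, poly[1, ])
  a <- closed[-nrow(closed), , drop = FALSE]
  b <- closed[-1, , drop = FALSE]
  ab <- b - a
  len2 <- pmax(rowSums(ab^2), 1e-300)
  d <- vapply(seq_len(nrow(pts)), function(i) {
    ap <- sweep(a, 2, pts[i, ], "-") * -1
    t_ <- pmin(pmax(rowSums(ap * ab) / len2, 0), 1)
    foot <- a + ab * t_
    sqrt(min(rowSums(sweep(foot, 2, pts[i, ])^2)))
  }, numeric(1))
  mean(d)
}

#' Tracking status for the AR overlay frame
#'
#' Maps marker visibility and reprojection RMS to the status indicator
#' colour: tracked (green) iff the marker is visible and the RMS does not
#' exceed the threshold (inclusive), otherwise lost (red).
#'
#' @param marker_visible logical.
#' @param reprojection_rms px.
#' @param threshold px (> 0, default 2).
#' @return List with `status` (`"tracked"`/`"lost"`) and `color`
#'   (`"green"`/`"red"`).
#' @export
tracking_status <- function(marker_visible, reprojection_rms,
                            threshold = 2.0) {
  stopifnot(threshold > 0)
  tracked <- isTRUE(marker_visible) && reprojection_rms <= threshold
  list(status = if (tracked) "tracked" else "lost",
       color = if (tracked) "green" else "red")
}
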