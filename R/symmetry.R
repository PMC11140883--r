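#' Estimate the midsagittal plane of a head mesh
#'
#' Finds the mirror-symmetry plane that underlies specular-ear planning.
#' The candidate plane is initialised from landmarks when available (the
#' perpendicular bisector of a left/right pair, or a plane through midline
#' points) and otherwise from the principal axis of least vertex variance
#' through the centroid (the left-right axis of a head). It is then
#' refined by mirror-ICP: a seeded random subsample of vertices is
#' reflected across the candidate plane, rigidly registered back onto the
#' mesh, and the mirror plane of the composed reflective transform is
#' extracted; this is iterated to convergence (change < 0.01 degrees in
#' the normal and < 0.01 mm in offset).
#'
#' @param head a [trimesh()] with at least 100 vertices.
#' @param landmarks optional [landmark_set()]. A left/right pair is
#'   detected from `_L`/`_R`, `_left`/`_right` name suffixes (e.g.
#'   `eye_L`/`eye_R`); otherwise all landmarks are treated as midline
#'   points when there are at least two.
#' @param seed integer seed for the vertex subsample.
#' @param subsample subsample size (default `min(5000, n)`).
#' @param max_iter maximum outer iterations (default 50).
#' @return A [plane()] with attributes `residual` (final mirror-ICP RMS in
#'   mm) and `iterations`.
#' @export
estimate_sagittal_plane <- function(head, landmarks = NULL, seed = 1L,
                                    subsample = 5000L, max_iter = 50L) {
  stopifnot(inherits(head, "trimesh"))
  v <- head$vertices
  if (nrow(v) < 100) stop("head mesh must have at least 100 vertices")
  cur <- init_sagittal_plane(v, landmarks)
  n_samp <- min(subsample, nrow(v))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  samp <- sample.int(nrow(v), n_samp)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  pts <- v[samp, , drop = FALSE]
  residual <- NA_real_
  for (it in seq_len(max_iter)) {
    refl <- reflect_across_plane(cur)
    mirrored <- iso_apply(refl, pts)
    fit <- icp(mirrored, head, max_iter = 30, tol_mm = 1e-5,
               reject_percentile = 90)
    residual <- fit$rms
    M <- iso_compose(fit$transform, refl)  # reflective
    new <- mirror_plane_of(M, reference_normal = cur$normal)
    dn <- angle_between_deg(cur$normal, new$normal)
    dd <- abs(cur$offset - new$offset)
    cur <- new
    if (dn < 0.01 && dd < 0.01) {
      attr(cur, "residual") <- residual
      attr(cur, "iterations") <- it
      return(cur)
    }
  }
  stop(sprintf(
    "sagittal plane estimation did not converge in %d iterations (last mirror-ICP rms %.4f mm)",
    max_iter, residual))
}

init_sagittal_plane <- function(v, landmarks) {
  if (!is.null(landmarks)) {
    stopifnot(inherits(landmarks, "landmark_set"))
    p <- landmarks$points
    nm <- tolower(rownames(p))
    base <- sub("(_l|_r|_left|_right)$", "", nm)
    side <- sub("^.*_", "", nm)
    lefts <- which(side %in% c("l", "left"))
    for (i in lefts) {
      j <- which(base == base[i] & side %in% c("r", "right"))
      if (length(j) == 1) {  # perpendicular bisector of the pair
        d <- p[j, ] - p[i, ]
        return(plane(d, sum((p[i, ] + p[j, ]) / 2 * d / sqrt(sum(d^2)))))
      }
    }
    if (nrow(p) >= 2) {
      # midline points: normal = least-variance axis of the mesh,
      # orthogonalised against the midline direction, through their mean
      dirs <- sweep(p, 2, colMeans(p))
      ax <- svd(dirs)$v[, 1]
      n0 <- eigen(stats::cov(v), symmetric = TRUE)$vectors[, 3]
      n0 <- n0 - sum(n0 * ax) * ax
      return(plane(n0, sum(colMeans(p) * n0 / sqrt(sum(n0^2)))))
    }
  }
  n0 <- eigen(stats::cov(v), symmetric = TRUE)$vectors[, 3]
  plane(n0, sum(colMeans(v) * n0))
}

# mirror plane of a (near-)reflective isometry: normal = eigenvector of
# the linear part for eigenvalue -1, offset from the translation component
mirror_plane_of <- function(M, reference_normal = NULL) {
  R <- M[1:3, 1:3]
  ev <- eigen(R)
  k <- which.min(abs(Re(ev$values) + 1) + abs(Im(ev$values)))
  n <- Re(ev$vectors[, k])
  n <- n / sqrt(sum(n^2))
  if (!is.null(reference_normal) && sum(n * reference_normal) < 0) n <- -n
  d <- sum(n * M[1:3, 4]) / 2
  plane(n, d)
}

angle_between_deg <- function(a, b) {
  c_ <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, c_)) * 180 / pi
}

#' Mirror-symmetry registration residual of a plane
#'
#' RMS point-to-surface distance of a seeded vertex subsample after
#' reflection across `plane` (no re-registration): the objective the
#' sagittal-plane search minimises up to the rigid correction. Exposed for
#' diagnostics and optimality checks.
#'
#' @inheritParams estimate_sagittal_plane
#' @param plane a [plane()].
#' @export
mirror_residual <- function(head, plane, seed = 1L, subsample = 2000L) {
  v <- head$vertices
  n_samp <- min(subsample, nrow(v))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  samp <- sample.int(nrow(v), n_samp)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  mirrored <- iso_apply(reflect_across_plane(plane),
                        v[samp, , drop = FALSE])
  sqrt(mean(mesh_closest_points(head, mirrored)$distance^2))
}

#' Crop a spherical region from a mesh
#'
#' Keeps the faces whose three vertices all lie within `radius` of
#' `center` and re-indexes vertices compactly; used to isolate an ear
#' around its landmark.
#'
#' @param mesh a [trimesh()].
#' @param center 3-vector (mm).
#' @param radius sphere radius (mm, > 0).
#' @return The cropped [trimesh()] with attribute `orig_vertex_index`
#'   mapping back into `mesh`.
#' @export
crop_region <- function(mesh, center, radius) {
  stopifnot(inherits(mesh, "trimesh"), radius > 0)
  d2 <- rowSums(sweep(mesh$vertices, 2, center)^2)
  inside <- d2 <= radius^2
  fkeep <- inside[mesh$faces[, 1]] & inside[mesh$faces[, 2]] &
    inside[mesh$faces[, 3]]
  if (!any(fkeep)) stop("empty crop: no face lies fully inside the sphere")
  f <- mesh$faces[fkeep, , drop = FALSE]
  vkeep <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[vkeep] <- seq_along(vkeep)
  out <- trimesh(mesh$vertices[vkeep, , drop = FALSE],
                 matrix(remap[f], ncol = 3),
                 paste0(mesh$name, "_crop"))
  attr(out, "orig_vertex_index") <- vkeep
  out
}

#' Build the specular (mirror-image) ear
#'
#' Reflects the healthy ear across the midsagittal plane; the result is
#' the plan-frame target ear in its ideal position. Winding is flipped by
#' the reflection machinery so the output stays outward-oriented.
#'
#' @param healthy_ear a [trimesh()] (typically an ear crop).
#' @param plane the midsagittal [plane()].
#' @return The mirrored [trimesh()].
#' @export
make_specular_ear <- function(healthy_ear, plane) {
  out <- apply_isometry(healthy_ear, reflect_across_plane(plane))
  out$name <- paste0(healthy_ear$name, "_specular")
  out
}
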