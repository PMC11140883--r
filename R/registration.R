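#' Registration results
#'
#' Container returned by [rigid_from_correspondences()], [icp()] and
#' [estimate_marker_pose()]: the fitted rigid [isometry()], the final
#' root-mean-square residual (mm for surface registration, px for pose
#' estimation), the iteration count, a convergence flag and the number of
#' correspondences used per iteration.
#'
#' @param transform rigid [isometry()].
#' @param rms final RMS residual (>= 0).
#' @param iterations number of iterations performed (>= 1).
#' @param converged logical.
#' @param correspondences_used integer vector, one entry per iteration.
#' @param rms_history numeric vector of per-iteration RMS values.
#' @return Object of class `registration_result`.
#' @export
registration_result <- function(transform, rms, iterations = 1L,
                                converged = TRUE,
                                correspondences_used = integer(0),
                                rms_history = numeric(0)) {
  stopifnot(inherits(transform, "isometry"),
            attr(transform, "kind") == "rigid",
            rms >= 0, iterations >= 1)
  structure(list(transform = transform, rms = rms,
                 iterations = as.integer(iterations),
                 converged = isTRUE(converged),
                 correspondences_used = as.integer(correspondences_used),
                 rms_history = as.numeric(rms_history)),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration: rms %.4g, %d iteration%s, %sconverged>\n",
              x$rms, x$iterations, if (x$iterations > 1) "s" else "",
              if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Closed-form rigid fit from point correspondences
#'
#' Weighted least-squares rigid transform mapping `source` onto `target`
#' (Kabsch/Umeyama via SVD of the weighted cross-covariance). Reflections
#' are excluded by construction: when the SVD solution has negative
#' determinant, the smallest singular direction is negated. This is the
#' closed-form solve underlying the splint-anchored "automatic
#' registration" and every ICP iteration.
#'
#' @param source,target n x 3 matrices of paired points (mm); n >= 3,
#'   non-collinear.
#' @param weights optional nonnegative per-pair weights.
#' @return A [registration_result()]; `rms` is the post-fit weighted RMS
#'   residual in mm.
#' @examples
#' src <- diag(3)
#' T <- rotation_isometry(c(0, 0, 1), 90)
#' fit <- rigid_from_correspondences(src, iso_apply(T, src))
#' fit$rms
#' @export
rigid_from_correspondences <- function(source, target, weights = NULL) {
  s <- as.matrix(source)
  t_ <- as.matrix(target)
  if (!identical(dim(s), dim(t_))) stop("source/target sizes differ")
  n <- nrow(s)
  if (n < 3) stop("need at least 3 correspondences")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) == 0)
    stop("weights must be nonnegative with positive sum")
  w <- w / sum(w)
  cs <- colSums(s * w)
  ct <- colSums(t_ * w)
  sc <- sweep(s, 2, cs)
  tc <- sweep(t_, 2, ct)
  H <- t(sc * w) %*% tc
  # degenerate when the weighted source points are (near) collinear
  sv_src <- svd(sc * sqrt(w))$d
  if (sv_src[2] <= 1e-12 * max(sv_src[1], 1))
    stop("degenerate correspondence geometry (collinear points)")
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- ct - R %*% cs
  T <- isometry(m, "rigid")
  resid <- iso_apply(T, s) - t_
  rms <- sqrt(sum(w * rowSums(resid^2)))
  registration_result(T, rms, iterations = 1L, converged = TRUE,
                      correspondences_used = n, rms_history = rms)
}

# resolve a mask spec into source-vertex indices
resolve_mask <- function(points, mask) {
  if (is.null(mask)) return(seq_len(nrow(points)))
  if (is.numeric(mask)) {
    idx <- as.integer(mask)
    if (length(idx) == 0 || any(idx < 1) || any(idx > nrow(points)))
      stop("mask index list empty or out of range")
    return(idx)
  }
  if (is.list(mask)) {
    centers <- mask$centers
    if (inherits(centers, "landmark_set")) centers <- centers$points
    centers <- as.matrix(centers)
    radius <- mask$radius %||% 25
    keep <- rep(FALSE, nrow(points))
    for (i in seq_len(nrow(centers))) {
      d2 <- rowSums(sweep(points, 2, centers[i, ])^2)
      keep <- keep | d2 <= radius^2
    }
    idx <- which(keep)
    if (length(idx) == 0) stop("mask selects no source vertices")
    return(idx)
  }
  stop("mask must be NULL, an index vector, or list(centers=, radius=)")
}

#' Iterative closest point surface registration
#'
#' Region-masked rigid ICP of a source mesh (or point set) onto a target
#' mesh, the reproducible stand-in for interactively aligning two scans
#' "with a focus on their most similar surfaces": iterate closest-point
#' matching (true point-to-surface foot points on target triangles),
#' rejection of correspondences above a residual percentile, and the
#' closed-form rigid fit. RMS is non-increasing across accepted
#' iterations; an iteration that would increase it is rejected and the
#' loop stops.
#'
#' @param source a [trimesh()] or an n x 3 point matrix.
#' @param target a [trimesh()] with at least one non-degenerate face.
#' @param init initial [isometry()] (default identity).
#' @param mask optional source-region selector: an integer index vector,
#'   or `list(centers = <k x 3 matrix or landmark_set>, radius = mm)`
#'   (union of spheres, default radius 25 mm, e.g. centred on the eye,
#'   forehead and nose landmarks).
#' @param max_iter maximum iterations (default 100).
#' @param tol_mm stop when the RMS improvement falls below this (default
#'   1e-4 mm).
#' @param reject_percentile correspondences with residuals above this
#'   percentile are dropped each iteration (default 90; 100 disables
#'   rejection).
#' @return A [registration_result()] whose `transform` maps source
#'   coordinates into the target frame.
#' @export
icp <- function(source, target, init = iso_identity(), mask = NULL,
                max_iter = 100, tol_mm = 1e-4, reject_percentile = 90) {
  stopifnot(inherits(target, "trimesh"))
  pts <- if (inherits(source, "trimesh")) source$vertices else as.matrix(source)
  idx <- resolve_mask(pts, mask)
  pts <- pts[idx, , drop = FALSE]
  if (nrow(pts) < 3) stop("fewer than 3 source points after masking")
  T <- init
  cp <- mesh_closest_points(target, iso_apply(T, pts))
  prev_rms <- Inf
  history <- numeric(0)
  used <- integer(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    res <- cp$distance
    if (any(!is.finite(res))) stop("non-finite ICP residuals")
    keep <- if (reject_percentile < 100) {
      thr <- quantile(res, reject_percentile / 100, names = FALSE)
      res <= thr
    } else rep(TRUE, length(res))
    if (sum(keep) < 3) stop("too few correspondences after rejection")
    cur <- iso_apply(T, pts)
    fit <- rigid_from_correspondences(cur[keep, , drop = FALSE],
                                      cp$foot[keep, , drop = FALSE])
    cand <- iso_compose(fit$transform, T)
    new_cp <- mesh_closest_points(target, iso_apply(cand, pts))
    new_rms <- sqrt(mean(new_cp$distance[keep]^2))
    if (new_rms > prev_rms) break  # keep the last accepted state
    T <- cand
    cp <- new_cp
    history <- c(history, new_rms)
    used <- c(used, sum(keep))
    improvement <- prev_rms - new_rms
    prev_rms <- new_rms
    if (improvement < tol_mm) {
      converged <- TRUE
      break
    }
  }
  if (length(history) == 0) {
    history <- sqrt(mean(cp$distance^2))
    used <- nrow(pts)
    prev_rms <- history
    converged <- TRUE
  }
  registration_result(T, prev_rms, iterations = length(history),
                      converged = converged, correspondences_used = used,
                      rms_history = history)
}
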