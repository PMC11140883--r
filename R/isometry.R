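#' Rigid and reflective isometries of 3-space
#'
#' An `isometry` is a 4x4 homogeneous transform acting on column points,
#' the universal currency for poses, registrations and mirroring. Its
#' upper-left 3x3 block is orthonormal; `kind` records whether it preserves
#' orientation (`"rigid"`, determinant +1) or reverses it (`"reflective"`,
#' determinant -1, e.g. the mirroring across the midsagittal plane).
#'
#' Composition follows the usual matrix convention: `iso_compose(A, B)`
#' applies `B` first, then `A`.
#'
#' @param matrix 4x4 numeric homogeneous matrix; bottom row `(0,0,0,1)`.
#' @param kind `"rigid"` or `"reflective"`; inferred from the determinant
#'   when missing.
#' @return An object of class `isometry`: the validated matrix with a
#'   `kind` attribute.
#' @examples
#' Tz <- rotation_isometry(c(0, 0, 1), 90)
#' p <- c(1, 0, 0)
#' iso_apply(Tz, p)  # ~ (0, 1, 0)
#' @export
isometry <- function(matrix, kind = NULL) {
  m <- as.matrix(matrix)
  if (!is.numeric(m) || !identical(dim(m), c(4L, 4L)))
    stop("isometry matrix must be a numeric 4x4 matrix")
  if (any(!is.finite(m))) stop("isometry matrix must be finite")
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-12)
    stop("isometry bottom row must be (0,0,0,1)")
  R <- m[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    stop("isometry linear part is not orthonormal")
  d <- det(R)
  inferred <- if (d > 0) "rigid" else "reflective"
  if (is.null(kind)) kind <- inferred
  kind <- match.arg(kind, c("rigid", "reflective"))
  if (kind != inferred)
    stop(sprintf("kind '%s' inconsistent with det(R) = %.3f", kind, d))
  structure(m, kind = kind, class = "isometry")
}

#' @export
print.isometry <- function(x, ...) {
  cat(sprintf("<isometry: %s>\n", attr(x, "kind")))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' @rdname isometry
#' @export
iso_identity <- function() isometry(diag(4), "rigid")

#' @rdname isometry
#' @param A,B isometries; `iso_compose(A, B)` applies `B` first.
#' @export
iso_compose <- function(A, B) {
  stopifnot(inherits(A, "isometry"), inherits(B, "isometry"))
  isometry(unclass(A) %*% unclass(B))
}

#' @rdname isometry
#' @export
iso_invert <- function(A) {
  stopifnot(inherits(A, "isometry"))
  R <- A[1:3, 1:3]
  t <- A[1:3, 4]
  m <- diag(4)
  m[1:3, 1:3] <- t(R)
  m[1:3, 4] <- -t(R) %*% t
  isometry(m, attr(A, "kind"))
}

#' @rdname isometry
#' @param T an isometry.
#' @param points a 3-vector or an n x 3 matrix of points (mm).
#' @export
iso_apply <- function(T, points) {
  stopifnot(inherits(T, "isometry"))
  p <- if (is.null(dim(points))) matrix(points, 1, 3) else as.matrix(points)
  stopifnot(ncol(p) == 3)
  out <- p %*% t(T[1:3, 1:3]) + rep(T[1:3, 4], each = nrow(p))
  if (is.null(dim(points))) drop(out) else out
}

#' @rdname isometry
#' @param axis rotation axis (3-vector, any nonzero length).
#' @param angle_deg rotation angle in degrees (right-hand rule).
#' @param center point the rotation pivots about (default origin).
#' @export
rotation_isometry <- function(axis, angle_deg, center = c(0, 0, 0)) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- center - R %*% center
  isometry(m, "rigid")
}

#' @rdname isometry
#' @param offset translation 3-vector (mm).
#' @export
translation_isometry <- function(offset) {
  m <- diag(4)
  m[1:3, 4] <- offset
  isometry(m, "rigid")
}

#' Oriented planes in 3-space
#'
#' A plane is stored in Hesse normal form `{x : n . x = d}` with a unit
#' normal `n` and offset `d` in mm; the normal orients the plane (used for
#' the midsagittal mirroring plane and for signed distances).
#'
#' @param normal 3-vector, any nonzero length (normalised on input).
#' @param offset scalar `d` for the *unit* normal. If `normal` is not unit
#'   length, `offset` is interpreted for the normalised normal unless
#'   `rescale_offset = TRUE`, in which case it is divided by the original
#'   norm (i.e. you supplied `n . x = d` for the unnormalised `n`).
#' @param rescale_offset see `offset`.
#' @return Object of class `plane` with fields `normal`, `offset`.
#' @examples
#' sagittal <- plane(c(1, 0, 0), 0)
#' plane_distance(sagittal, c(5, 1, 1))  # 5 mm to the right
#' @export
plane <- function(normal, offset = 0, rescale_offset = FALSE) {
  n <- as.numeric(normal)
  stopifnot(length(n) == 3, all(is.finite(n)), is.finite(offset))
  len <- sqrt(sum(n^2))
  if (len == 0) stop("plane normal must be nonzero")
  structure(list(normal = n / len,
                 offset = if (rescale_offset) offset / len else offset),
            class = "plane")
}

#' @export
print.plane <- function(x, ...) {
  cat(sprintf("<plane: n = (%.4f, %.4f, %.4f), d = %.4f mm>\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset))
  invisible(x)
}

#' @rdname plane
#' @param x a `plane`.
#' @param points 3-vector or n x 3 matrix.
#' @return `plane_distance()`: signed distances `n . x - d` (mm).
#' @export
plane_distance <- function(x, points) {
  p <- if (is.null(dim(points))) matrix(points, 1, 3) else as.matrix(points)
  drop(p %*% x$normal) - x$offset
}

#' Reflection across a plane
#'
#' Builds the reflective isometry with linear part `I - 2 n n'` and
#' translation `2 d n`: the Householder mirror used to generate the
#' specular (mirror-image) ear across the midsagittal plane. Applying it
#' twice is the identity.
#'
#' @param plane a [plane()].
#' @return A reflective [isometry()].
#' @examples
#' R <- reflect_across_plane(plane(c(1, 0, 0), 0))
#' iso_apply(R, c(1, 2, 3))  # (-1, 2, 3)
#' @export
reflect_across_plane <- function(plane) {
  n <- plane$normal
  m <- diag(4)
  m[1:3, 1:3] <- diag(3) - 2 * tcrossprod(n)
  m[1:3, 4] <- 2 * plane$offset * n
  isometry(m, "reflective")
}

#' Read and write transforms as JSON
#'
#' Transforms are exchanged as JSON objects with a row-major list of 16
#' floats and a `kind` field.
#'
#' @param path file path.
#' @return `read_transform()` returns an [isometry()].
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$matrix) || length(x$matrix) != 16)
    stop("transform JSON must contain a 16-element 'matrix'")
  m <- matrix(as.numeric(x$matrix), 4, 4, byrow = TRUE)
  isometry(m, x$kind %||% NULL)
}

#' @rdname read_transform
#' @param T an [isometry()].
#' @export
write_transform <- function(T, path) {
  stopifnot(inherits(T, "isometry"))
  jsonlite::write_json(
    list(matrix = as.numeric(t(unclass(T))), kind = attr(T, "kind")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# angle (deg) between the rotations of two isometries
iso_rotation_angle_deg <- function(A, B = iso_identity()) {
  R <- t(B[1:3, 1:3]) %*% A[1:3, 1:3]
  c_ <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, c_))) * 180 / pi
}
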