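#' Triangle surface meshes
#'
#' The container for every head, ear and plan model: an n x 3 matrix of
#' vertex coordinates (mm, right-handed RAS frame) and an m x 3 integer
#' matrix of 1-based vertex indices per triangle. Counter-clockwise winding
#' (seen from outside) is the outward-normal convention, so a closed mesh
#' has positive signed volume. Zero-area faces are retained but flagged
#' (scanner exports contain them); distance queries skip them.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param name free-text label.
#' @return Object of class `trimesh` with fields `vertices`, `faces`,
#'   `name` and a logical `degenerate` flag per face.
#' @examples
#' tet <- trimesh(rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1)),
#'                rbind(c(1,3,2), c(1,2,4), c(1,4,3), c(2,3,4)),
#'                name = "tetrahedron")
#' mesh_volume(tet)  # 1/6
#' @export
trimesh <- function(vertices, faces, name = "mesh") {
  v <- as.matrix(vertices)
  f <- as.matrix(faces)
  storage.mode(v) <- "double"
  storage.mode(f) <- "integer"
  if (ncol(v) != 3) stop("vertices must have 3 columns")
  if (ncol(f) != 3) stop("faces must have 3 columns")
  if (nrow(f) < 1) stop("empty mesh: no faces")
  if (any(!is.finite(v))) stop("vertex coordinates must be finite")
  if (any(f < 1L) || any(f > nrow(v)))
    stop("face indices out of range")
  if (any(f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]))
    stop("faces must not repeat a vertex")
  dimnames(v) <- NULL
  dimnames(f) <- NULL
  m <- structure(list(vertices = v, faces = f, name = as.character(name)),
                 class = "trimesh")
  m$degenerate <- face_areas(m) < .au_tol$degenerate_area
  m
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh '%s': %d vertices, %d faces%s>\n",
              x$name, nrow(x$vertices), nrow(x$faces),
              if (any(x$degenerate))
                sprintf(", %d degenerate", sum(x$degenerate)) else ""))
  invisible(x)
}

#' Mesh metrics
#'
#' `mesh_volume()` is the signed volume from the divergence theorem
#' (positive for a closed, outward-oriented mesh); `mesh_area()` the total
#' surface area; `face_areas()` and `face_normals()` the per-face
#' quantities (unit normals; zero rows for degenerate faces);
#' `mesh_centroid()` the vertex mean.
#'
#' @param mesh a [trimesh()].
#' @return Numeric scalar, vector or matrix as appropriate.
#' @export
mesh_volume <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c_ <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' @rdname mesh_volume
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' @rdname mesh_volume
#' @export
face_areas <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  e1 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE] - a
  e2 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sqrt(rowSums(cr^2)) / 2
}

#' @rdname mesh_volume
#' @export
face_normals <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  e1 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE] - a
  e2 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(cr^2))
  len[len == 0] <- Inf
  cr / len
}

#' @rdname mesh_volume
#' @export
mesh_centroid <- function(mesh) colMeans(mesh$vertices)

#' Transform a mesh by an isometry
#'
#' Maps every vertex by `T`. For a reflective `T` the face winding is
#' flipped so the outward-normal convention (positive signed volume for a
#' closed mesh) is preserved.
#'
#' @param mesh a [trimesh()].
#' @param T an [isometry()].
#' @return The transformed [trimesh()].
#' @export
apply_isometry <- function(mesh, T) {
  stopifnot(inherits(mesh, "trimesh"), inherits(T, "isometry"))
  v <- iso_apply(T, mesh$vertices)
  f <- mesh$faces
  if (attr(T, "kind") == "reflective") f <- f[, c(1, 3, 2), drop = FALSE]
  trimesh(v, f, mesh$name)
}

#' Edge-manifold check
#'
#' TRUE when every edge is shared by exactly two faces (a closed,
#' edge-manifold surface, possibly with several components).
#'
#' @param mesh a [trimesh()].
#' @export
is_closed_mesh <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

# closest points on mesh surface for query points; skips degenerate faces
mesh_closest_points <- function(mesh, points) {
  q <- if (is.null(dim(points))) matrix(points, 1, 3) else as.matrix(points)
  if (all(mesh$degenerate)) stop("mesh has no non-degenerate faces")
  res <- cp_mesh_query(mesh$vertices, mesh$faces - 1L,
                       !mesh$degenerate, q)
  res
}
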