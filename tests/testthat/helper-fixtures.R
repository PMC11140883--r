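# Shared fixtures and small geometry helpers. Heavier synthetic objects are
# generated once per test run and memoised here.

.fixtures <- new.env(parent = emptyenv())

# standard symmetric synthetic head (default study conditions)
test_head <- function() {
  if (is.null(.fixtures$head)) .fixtures$head <- make_head(synth_spec())
  .fixtures$head
}

unit_tetrahedron <- function() {
  trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
          rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)),
          name = "tetrahedron")
}

unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  dimnames(v) <- NULL
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),  # z = 0
    c(5, 6, 7), c(6, 8, 7),  # z = 1
    c(1, 2, 5), c(2, 6, 5),  # y = 0
    c(3, 7, 4), c(4, 7, 8),  # y = 1
    c(1, 5, 3), c(3, 5, 7),  # x = 0
    c(2, 4, 6), c(4, 8, 6))  # x = 1
  trimesh(v, f, name = "cube")
}

# seeded random rigid transform with bounded magnitude
random_rigid <- function(max_angle_deg = 20, max_trans = 10) {
  ax <- rnorm(3)
  iso_compose(translation_isometry(runif(3, -max_trans, max_trans)),
              rotation_isometry(ax, runif(1, -max_angle_deg, max_angle_deg)))
}

# seeded random tetrahedral mesh (non-degenerate with probability 1)
random_tetra_mesh <- function(scale = 50) {
  repeat {
    v <- matrix(runif(12, -scale, scale), 4, 3)
    m <- tryCatch(trimesh(v, rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3),
                                   c(2, 3, 4))),
                  error = function(e) NULL)
    if (!is.null(m) && !any(m$degenerate)) {
      if (mesh_volume(m) < 0) m <- trimesh(m$vertices, m$faces[, c(1, 3, 2)])
      return(m)
    }
  }
}

rotation_error_deg <- function(A, B) {
  R <- t(A[1:3, 1:3]) %*% B[1:3, 1:3]
  acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

translation_error_mm <- function(A, B) sqrt(sum((A[1:3, 4] - B[1:3, 4])^2))

default_test_camera <- function() camera_model(1000, 1000, 640, 360,
                                               c(1280, 720))
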