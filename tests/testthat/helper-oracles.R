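# Independent brute-force oracles used to validate the closed-form and
# compiled implementations.

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a),
                              0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0,
                              sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                              0, 0, 1), 3, 3)

# exhaustive rigid-fit oracle: Euler-angle grid search with translation by
# centroid matching; two-stage (coarse box, then fine box around the coarse
# optimum) so the discretisation error is far below the comparison tolerance
oracle_rigid_grid_rms <- function(source, target,
                                  box_deg = 12, coarse_deg = 1,
                                  fine_deg = 0.05) {
  cs <- colMeans(source)
  ct <- colMeans(target)
  sc <- sweep(source, 2, cs)
  tc <- sweep(target, 2, ct)
  grid_rms <- function(center, half, step) {
    angs <- lapply(1:3, function(k)
      seq(center[k] - half, center[k] + half, by = step))
    best <- Inf
    best_ang <- center
    for (a in angs[[1]]) for (b in angs[[2]]) for (g in angs[[3]]) {
      R <- rot_z(a * pi / 180) %*% rot_y(b * pi / 180) %*%
        rot_x(g * pi / 180)
      res <- sc %*% t(R) - tc
      rms <- sqrt(mean(rowSums(res^2)))
      if (rms < best) {
        best <- rms
        best_ang <- c(a, b, g)
      }
    }
    list(rms = best, ang = best_ang)
  }
  coarse <- grid_rms(c(0, 0, 0), box_deg, coarse_deg)
  fine <- grid_rms(coarse$ang, coarse_deg, fine_deg)
  fine$rms
}

# exhaustive pairwise caliper diameter via stats::dist
oracle_diameter <- function(vertices) {
  max(stats::dist(vertices))
}
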