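# shared fixtures and independent oracles

# n ordered samples of a circle of radius r in the plane spanned by (u, v)
# about `center`
circle_ring_points <- function(n = 300, r = 1, center = c(0, 0, 0),
                               u = c(1, 0, 0), v = c(0, 1, 0)) {
  a <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  t(center + outer(u, cos(a)) * r + outer(v, sin(a)) * r)
}

# closed unit-cube triangle mesh with outward winding
unit_cube_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  f <- rbind(c(1, 3, 2), c(1, 4, 3), c(5, 6, 7), c(5, 7, 8),
             c(1, 2, 6), c(1, 6, 5), c(2, 3, 7), c(2, 7, 6),
             c(3, 4, 8), c(3, 8, 7), c(4, 1, 5), c(4, 5, 8))
  tri_mesh(v, f)
}

# regular tetrahedron on the unit corner (volume 1/6), outward winding
corner_tetra_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  tri_mesh(v, f)
}

# random proper rotation matrix
random_rotation <- function() {
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# divergence-theorem volume of a closed mesh: independent surface-integral
# route (flux of F = (x, 0, 0) through the boundary)
divergence_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]   # 2 * area * normal_x
  cx <- (p1[, 1] + p2[, 1] + p3[, 1]) / 3
  abs(sum(cx * nx / 2))
}

# exact two-sided one-sample signed-rank p by enumeration of all 2^n sign
# assignments (zero differences must be removed, no tied |d| allowed)
enum_signed_rank_p <- function(d) {
  n <- length(d)
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.vector(signs %*% rk)
  min(1, 2 * min(mean(Vs >= V), mean(Vs <= V)))
}

# brute-force runs-test threshold selection: naive loop over the candidate
# grid, counting runs with rle()
oracle_runs_threshold <- function(env, perm, grid) {
  rle_runs <- function(x, t) length(rle(x > t)$lengths)
  best <- -Inf; sel <- grid[1]
  for (t in grid) {
    d <- rle_runs(env[perm], t) - rle_runs(env, t)
    if (d > best) { best <- d; sel <- t }
  }
  sel
}

# event-marker style trajectory: smooth retraction with curvature-matched
# anterior drift before the peak and rebound after the trough
event_path <- function(t, x_on, A, t_on, t_off)
  hyolingual:::event_x_path(t, x_on, A, t_on, t_off)
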