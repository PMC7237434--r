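test_that("coronal spline rings interpolate their controls with stable closure", {
  cp <- rbind(c(0, -1, 0), c(0, 0, -1), c(0, 1, 0), c(0, 0, 1))
  ring <- fit_coronal_ring(cp)
  expect_equal(nrow(ring$points), 300)
  # each control lies on the retained middle loop
  for (i in 1:4)
    expect_lt(min(sqrt(rowSums(sweep(ring$points, 2, cp[i, ])^2))), 1e-6)
  # symmetric controls give a ring symmetric under 90-degree rotation up to
  # the natural-spline end conditions of the wrapped fit: retaining the
  # middle of three loops suppresses, but cannot fully remove, the end
  # effect, leaving a residual ~1e-3 of the ring radius
  R90 <- rbind(c(1, 0, 0), c(0, 0, -1), c(0, 1, 0))   # rotate in the ring plane
  rot <- ring$points %*% t(R90)
  mismatch <- max(apply(rot, 1, function(p)
    min(sqrt(rowSums(sweep(ring$points, 2, p)^2)))))
  expect_lt(mismatch, 2e-3)
  expect_error(fit_coronal_ring(cp[c(1, 1, 2, 3), ]), "duplicate")
})

test_that("ring through circle controls has near-circular circumference", {
  r <- 7
  cp <- rbind(c(0, -r, 0), c(0, 0, -r), c(0, r, 0), c(0, 0, r))
  ring <- fit_coronal_ring(cp)
  expect_lt(abs(ring_circumference(ring) / (2 * pi * r) - 1), 0.02)
})

test_that("equal-arc-length resampling is uniform and correspondence-preserving", {
  circ <- coronal_ring(circle_ring_points(300, r = 2, u = c(0, 1, 0), v = c(0, 0, 1)))
  p4 <- resample_ring(circ, 8)
  # 45-degree spacing on a circle
  ang <- atan2(p4[, 3], p4[, 2])
  expect_equal(max(abs(diff(ang)[abs(diff(ang)) < pi] %% (2 * pi) - pi / 4)), 0,
               tolerance = 1e-6)
  # equal-arc contract: consecutive arc lengths have tiny CV
  p <- resample_ring(circ, 100)
  seg <- sqrt(rowSums((rbind(p[-1, ], p[1, ]) - p)^2))
  expect_lt(stats::sd(seg) / mean(seg), 1e-3)
  # matched congruent parallel circles give equal-length connecting segments
  circ2 <- coronal_ring(circle_ring_points(300, r = 2, center = c(-5, 0, 0),
                                           u = c(0, 1, 0), v = c(0, 0, 1)))
  rs <- resample_matched_rings(circ, circ2, n = 64)
  conn <- sqrt(rowSums((rs$middle - rs$posterior)^2))
  expect_lt(max(conn) - min(conn), 1e-6)
})

test_that("opposite-handed rings are auto-reversed into a common orientation", {
  pts <- circle_ring_points(300, r = 2, u = c(0, 1, 0), v = c(0, 0, 1))
  rev_pts <- pts[c(1, 300:2), ]                     # opposite winding
  rs <- resample_matched_rings(coronal_ring(pts), coronal_ring(rev_pts), n = 32)
  conn <- sqrt(rowSums((rs$middle - rs$posterior)^2))
  expect_lt(max(conn), 1e-6)                        # same points after reversal
})

test_that("harmonic fill of a planar ring is exactly planar with harmonic interior", {
  cp <- rbind(c(5, -3, 0), c(5, 0, -4), c(5, 3, 0), c(5, 0, 4))
  ring <- fit_coronal_ring(cp)
  surf <- fill_harmonic_surface(ring)
  expect_lt(max(abs(surf$mesh$vertices[, 1] - 5)), 1e-8)
  expect_lt(max(harmonic_residual(surf)), 1e-8)
})

test_that("saddle boundary fills to the exact harmonic span within 1e-3", {
  a <- seq(0, 2 * pi, length.out = 301)[1:300]
  sad <- cbind(cos(a), sin(a), cos(a) * sin(a))     # z = xy, harmonic
  surf <- fill_harmonic_surface(coronal_ring(sad))
  V <- surf$mesh$vertices
  relerr <- max(abs(V[, 3] - V[, 1] * V[, 2])) / max(abs(sad[, 3]))
  expect_lt(relerr, 1e-3)
  # discrete maximum principle per coordinate
  ii <- setdiff(seq_len(nrow(V)), surf$boundary_idx)
  for (k in 1:3) {
    expect_gte(min(V[ii, k]), min(sad[, k]) - 1e-9)
    expect_lte(max(V[ii, k]), max(sad[, k]) + 1e-9)
  }
})

test_that("interior refinement changes enclosed volumes by well under 0.5 percent", {
  a <- seq(0, 2 * pi, length.out = 301)[1:300]
  sad <- cbind(3 * cos(a), 3 * sin(a), 1.5 * cos(a) * sin(a))
  apex <- c(0, 0, 8)
  v1 <- signed_mesh_volume(
    hyolingual:::cone_mesh(fill_harmonic_surface(coronal_ring(sad), density = 1), apex))
  v2 <- signed_mesh_volume(
    hyolingual:::cone_mesh(fill_harmonic_surface(coronal_ring(sad), density = 0.5), apex))
  expect_lt(abs(v2 / v1 - 1), 0.005)
})

test_that("primitive meshes are watertight with sphere topology and match closed forms", {
  circ <- coronal_ring(circle_ring_points(300, 2, u = c(0, 1, 0), v = c(0, 0, 1)))
  circ2 <- coronal_ring(circle_ring_points(300, 2, center = c(-5, 0, 0),
                                           u = c(0, 1, 0), v = c(0, 0, 1)))
  rs <- resample_matched_rings(circ, circ2, n = 300)
  sm <- fill_harmonic_surface(coronal_ring(rs$middle))
  sp <- fill_harmonic_surface(coronal_ring(rs$posterior))
  pr <- build_primitives(sm, sp, c(3, 0, 0), c(-8, 0, 0))
  for (m in pr) {
    expect_true(is_closed_mesh(m))
    expect_equal(euler_characteristic(m), 2L)
  }
  expect_lt(abs(signed_mesh_volume(pr$aot) / (pi * 4 * 3 / 3) - 1), 0.01)
  expect_lt(abs(signed_mesh_volume(pr$pot) / (pi * 4 * 5) - 1), 0.01)
  expect_lt(abs(signed_mesh_volume(pr$tb) / (pi * 4 * 3 / 3) - 1), 0.01)
  # missing vallecular marker omits the TB mesh
  pr2 <- build_primitives(sm, sp, c(3, 0, 0), NULL)
  expect_null(pr2$tb)
})

test_that("signed mesh volume matches closed forms and an independent surface-integral oracle", {
  expect_equal(signed_mesh_volume(unit_cube_mesh()), 1)
  expect_equal(signed_mesh_volume(corner_tetra_mesh()), 1 / 6)
  # random closed convex-hull-like mesh: sphere triangulation via primitives
  circ <- coronal_ring(circle_ring_points(200, 3, u = c(0, 1, 0), v = c(0, 0, 1)))
  cone <- hyolingual:::cone_mesh(fill_harmonic_surface(circ), c(5, 0.5, -0.3))
  expect_equal(signed_mesh_volume(cone), divergence_volume(cone), tolerance = 1e-12)
  # reference-origin independence for closed meshes
  set.seed(8)
  v0 <- signed_mesh_volume(cone)
  for (i in 1:10) {
    o <- rnorm(3, sd = 50)
    expect_equal(signed_mesh_volume(cone, origin = o), v0, tolerance = 1e-9)
  }
  expect_warning(signed_mesh_volume(tri_mesh(corner_tetra_mesh()$vertices,
                                             corner_tetra_mesh()$faces[1:3, ])),
                 "not closed")
})

test_that("regional volumes are deterministic, rigid-invariant, and scale cubically", {
  base <- hyolingual:::tongue_baseline()
  nfr <- 3
  co <- array(rep(base, each = nfr), c(nfr, nrow(base), 3))
  ms <- marker_set(co, rownames(base), 200)
  hd <- matrix(rep(hyolingual:::hyoid_dorsal_baseline(), each = nfr), nfr)
  rv <- regional_volumes(ms, hd, n_ring = 150, density = 2)
  # static constellation: constant volumes
  for (col in c("aot_ml", "pot_ml", "tb_ml"))
    expect_lt(diff(range(rv[[col]])) / mean(rv[[col]]), 1e-9)
  # rigid translation leaves volumes unchanged
  co2 <- co + 100
  rv2 <- regional_volumes(marker_set(co2, rownames(base), 200), hd + 100,
                          frames = 1, n_ring = 150, density = 2)
  expect_equal(unlist(rv2[1, 2:4]), unlist(rv[1, 2:4]), tolerance = 1e-9)
  # uniform scaling by c scales volumes by c^3
  for (s in c(0.5, 2)) {
    rvs <- regional_volumes(marker_set(co * s, rownames(base), 200), hd * s,
                            frames = 1, n_ring = 150, density = 2)
    expect_equal(unlist(rvs[1, 2:4]), unlist(rv[1, 2:4]) * s^3, tolerance = 1e-6)
  }
})

test_that("ring sample count is converged: n=150 and n=300 volumes differ under 1 percent", {
  base <- hyolingual:::tongue_baseline()
  co <- array(rep(base, each = 1), c(1, nrow(base), 3))
  ms <- marker_set(co, rownames(base), 200)
  hd <- matrix(hyolingual:::hyoid_dorsal_baseline(), 1)
  v150 <- regional_volumes(ms, hd, n_ring = 150)
  v300 <- regional_volumes(ms, hd, n_ring = 300)
  for (col in c("aot_ml", "pot_ml", "tb_ml"))
    expect_lt(abs(v150[[col]] / v300[[col]] - 1), 0.01)
})

test_that("per-frame geometry failures yield NA volumes and the pipeline continues", {
  base <- hyolingual:::tongue_baseline()
  co <- marker_set(array(rep(base, each = 2), c(2, nrow(base), 3)),
                   rownames(base), 200)$coords
  co[1, "middle_deep", ] <- NA                       # frame 1 unusable
  ms <- marker_set(co, rownames(base), 200)
  hd <- matrix(rep(hyolingual:::hyoid_dorsal_baseline(), each = 2), 2)
  rv <- regional_volumes(ms, hd, n_ring = 150, density = 2)
  expect_true(is.na(rv$aot_ml[1]))
  expect_false(is.na(rv$aot_ml[2]))
})
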