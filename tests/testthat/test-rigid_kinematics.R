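ref_cluster <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 8, 0), c(3, 2, 6),
                     c(-4, 5, 1), c(2, -6, 3), c(7, 7, -2), c(-3, -3, -3))

test_that("pose estimation recovers identity and known transforms", {
  p <- estimate_pose(ref_cluster, ref_cluster)
  expect_equal(p$R, diag(3), tolerance = 1e-12)
  expect_equal(p$t, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(p$residual_rms, 0, tolerance = 1e-12)

  th <- 10 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr <- c(1, 2, 3)
  obs <- sweep(ref_cluster %*% t(R), 2, tr, `+`)
  p <- estimate_pose(ref_cluster, obs)
  expect_equal(p$R, R, tolerance = 1e-9)
  expect_equal(p$t, tr, tolerance = 1e-9)
})

test_that("pose estimation under isotropic noise recovers translation and reports residual ~ sigma", {
  set.seed(101)
  R <- random_rotation(); tr <- c(4, -2, 7)
  terr <- numeric(1000); res <- numeric(1000)
  for (i in 1:1000) {
    obs <- sweep(ref_cluster %*% t(R), 2, tr, `+`) +
      matrix(rnorm(24, sd = 0.05), ncol = 3)
    p <- estimate_pose(ref_cluster, obs)
    terr[i] <- sqrt(sum((p$t - tr)^2))
    res[i] <- p$residual_rms
  }
  expect_lt(stats::median(terr), 0.05)
  expect_equal(mean(res), 0.05, tolerance = 0.15)
})

test_that("pose estimation is equivariant under marker relabeling and rigid pre-transforms", {
  set.seed(3)
  R <- random_rotation(); tr <- rnorm(3)
  obs <- sweep(ref_cluster %*% t(R), 2, tr, `+`)
  perm <- sample(nrow(ref_cluster))
  p1 <- estimate_pose(ref_cluster, obs)
  p2 <- estimate_pose(ref_cluster[perm, ], obs[perm, ])
  expect_equal(p1$R, p2$R, tolerance = 1e-9)
  expect_equal(p1$t, p2$t, tolerance = 1e-9)
  # pre-rotating the bone-fixed frame composes as expected
  Q <- random_rotation()
  p3 <- estimate_pose(ref_cluster %*% t(Q), obs)
  expect_equal(p3$R, R %*% t(Q), tolerance = 1e-9)
  expect_error(estimate_pose(ref_cluster[1:2, ], obs[1:2, ]), "insufficient")
  col3 <- cbind(1:4, 2 * (1:4), -1 * (1:4))
  expect_error(estimate_pose(col3, col3), "collinear")
})

make_pitch_pose <- function(thetas, pivot = c(2, 2, 0), ref = ref_cluster) {
  nfr <- length(thetas)
  obs <- array(NA_real_, c(nfr, nrow(ref), 3))
  for (f in seq_len(nfr)) {
    a <- -thetas[f] * pi / 180
    R <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
    obs[f, , ] <- sweep(sweep(ref, 2, pivot) %*% t(R), 2, pivot, `+`)
  }
  pose_series(ref, marker_set(obs, paste0("m", 1:nrow(ref)), 200))
}

test_that("gape pitch angle recovers programmed rotations about Z", {
  pose <- make_pitch_pose(c(0, 5, 2, 0))
  g <- gape_pitch_angle(pose)
  expect_equal(g, c(0, 5, 2, 0), tolerance = 1e-9)
  # pitch is invariant to the choice of bone-fixed marker subset (noise-free)
  pose_sub <- make_pitch_pose(c(0, 5, 2, 0), ref = ref_cluster[1:5, ])
  expect_equal(gape_pitch_angle(pose_sub), g, tolerance = 1e-9)
})

test_that("pure translation yields zero pitch at all frames", {
  nfr <- 6
  obs <- array(NA_real_, c(nfr, nrow(ref_cluster), 3))
  for (f in seq_len(nfr))
    obs[f, , ] <- sweep(ref_cluster, 2, c(f, -f, 2 * f), `+`)
  pose <- pose_series(ref_cluster, marker_set(obs, paste0("m", 1:8), 200))
  expect_equal(gape_pitch_angle(pose), rep(0, nfr), tolerance = 1e-9)
})

test_that("hyoid excursion reports delta X/Y relative to the reference frame", {
  xyz <- matrix(rep(c(20, -10, 0), each = 5), ncol = 3)
  he <- hyoid_excursion(xyz)
  expect_equal(he$protraction, rep(0, 5))
  expect_equal(he$elevation, rep(0, 5))
  # displacement matching the in vivo mean excursion targets
  xyz2 <- xyz; xyz2[5, ] <- xyz2[5, ] + c(4.23, 2.13, 0)
  he2 <- hyoid_excursion(xyz2)
  expect_equal(he2$protraction[5], 4.23)
  expect_equal(he2$elevation[5], 2.13)
  # linearity: sinusoidal X maps to sinusoidal protraction, same amplitude
  t <- seq(0, 1, length.out = 100)
  xyz3 <- cbind(3 * sin(2 * pi * t), 0, 0)
  he3 <- hyoid_excursion(xyz3, reference_frame = 1)
  expect_equal(he3$protraction, 3 * sin(2 * pi * t), tolerance = 1e-12)
  expect_error(hyoid_excursion(xyz, reference_frame = 99), "reference")
})

test_that("pooled SD matches its closed form and is monotone", {
  expect_equal(pooled_sd(c(0.3, 0.3, 0.3, 0.3)), 0.3)
  expect_equal(round(pooled_sd(c(0.06, 0.04, 0.08, 0.05)), 4), 0.0594)
  expect_equal(pooled_sd(0), 0)
  expect_equal(pooled_sd(0.42), 0.42)            # single-animal identity
  expect_lt(pooled_sd(c(0.05, 0.05)), pooled_sd(c(0.05, 0.08)))
  expect_error(pooled_sd(numeric(0)))
})

test_that("zero-velocity band is +/- 2 SD, homogeneous, and degenerate-safe", {
  set.seed(5)
  v <- rnorm(1e4, sd = 0.1)
  b <- zero_velocity_band(v)
  expect_lt(abs(b[2] / 0.2 - 1), 0.05)                    # within 5%
  expect_equal(b[1], -b[2])
  expect_equal(zero_velocity_band(3 * v), 3 * b, tolerance = 1e-12)
  expect_warning(bz <- zero_velocity_band(rep(0, 100)), "constant")
  expect_equal(bz, c(0, 0))
})
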