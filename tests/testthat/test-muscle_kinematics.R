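two_marker_set <- function(a, b, frames = 1) {
  co <- array(NA_real_, c(frames, 2, 3))
  for (f in seq_len(frames)) { co[f, 1, ] <- a; co[f, 2, ] <- b }
  marker_set(co, c("org", "ins"), 200)
}

test_that("muscle length is the Euclidean attachment distance, missing-safe", {
  ms <- two_marker_set(c(0, 0, 0), c(3, 4, 0))
  expect_equal(muscle_length(muscle_def("m", "org", "ins"), ms), 5)
  # marker-to-reconstructed-point definition
  expect_equal(muscle_length(muscle_def("m", c(0, 0, 0), "ins"), ms), 5)
  ms$coords[1, 2, 2] <- NA
  expect_true(is.na(muscle_length(muscle_def("m", "org", "ins"), ms)))
  expect_error(muscle_length(muscle_def("m", "org", "nope"), ms), "unknown")
})

test_that("lengths and tongue dimensions are invariant under joint rigid transforms", {
  set.seed(11)
  base <- hyolingual:::tongue_baseline()
  co <- array(rep(base, each = 2), c(2, nrow(base), 3))
  ms <- marker_set(co, rownames(base), 200)
  hd <- matrix(rep(hyolingual:::hyoid_dorsal_baseline(), each = 2), 2)
  L0 <- muscle_length(muscle_def("m", "anterior", "posterior_surface"), ms)
  d0 <- tongue_dimensions(ms, hd)
  R <- random_rotation(); tr <- rnorm(3, sd = 20)
  co2 <- co
  for (j in seq_len(dim(co)[2])) co2[, j, ] <- sweep(co[, j, ] %*% t(R), 2, tr, `+`)
  ms2 <- marker_set(co2, rownames(base), 200)
  hd2 <- sweep(hd %*% t(R), 2, tr, `+`)
  expect_equal(muscle_length(muscle_def("m", "anterior", "posterior_surface"), ms2),
               L0, tolerance = 1e-9)
  # dimensions are axis projections: transform the frame along with the data
  fr <- structure(list(origin = tr, axes = R), class = "anatomical_frame")
  expect_equal(tongue_dimensions(markers_to_frame(ms2, fr), to_frame(hd2, fr)),
               d0, tolerance = 1e-8)
})

test_that("programmed styloglossus shortening is recovered exactly from its ramp", {
  o <- c(20, 15, 12); i0 <- c(30, 4, 9)
  u <- (o - i0) / sqrt(sum((o - i0)^2))
  ramp <- (1 - cos(pi * seq(0, 1, length.out = 50))) / 2
  co <- array(NA_real_, c(50, 1, 3))
  for (k in 1:3) co[, 1, k] <- i0[k] + u[k] * 0.76 * ramp
  ms <- marker_set(co, "ins", 200)
  len <- muscle_length(muscle_def("styloglossus", o, "ins"), ms)
  expect_equal(len[50] - len[1], -0.76, tolerance = 1e-9)
})

test_that("sagittal angle follows the anterior=0 / superior=90 / posterior=180 convention", {
  mk <- function(dir) two_marker_set(dir, c(0, 0, 0))   # insertion at origin
  def <- muscle_def("m", "org", "ins")
  expect_equal(sagittal_angle(def, mk(c(-1, 0, 0))), 180)
  expect_equal(sagittal_angle(def, mk(c(0, 1, 0))), 90)
  expect_equal(sagittal_angle(def, mk(c(0, -1, 0))), 270)
  expect_equal(sagittal_angle(def, mk(c(-1, -1, 0))), 225)
  expect_equal(sagittal_angle(def, mk(c(1, 0, 0))), 0)
  # v and -v differ by exactly 180
  set.seed(2)
  for (i in 1:10) {
    d <- rnorm(3)
    a1 <- sagittal_angle(def, mk(d))
    a2 <- sagittal_angle(def, mk(-d))
    expect_equal((a1 - a2) %% 360, 180, tolerance = 1e-9)
  }
  # zero sagittal projection flagged undefined
  expect_true(is.na(sagittal_angle(def, mk(c(0, 0, 1)))))
  # posterior band convention
  expect_true(is_posterior_oriented(180))
  expect_true(is_posterior_oriented(150))
  expect_false(is_posterior_oriented(90))
  expect_false(is_posterior_oriented(270))
})

test_that("contraction states combine velocity band and activity gate", {
  band <- c(-0.2, 0.2)
  v <- c(0, -5, -5, 5, 0.1, NA)
  act <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  st <- classify_state(v, band, act)
  expect_equal(as.character(st),
               c("isometric", "concentric", "inactive", "eccentric",
                 "inactive", NA))
  expect_error(classify_state(v, c(0.2, -0.2), act), "band")
})

test_that("tongue dimensions are axis-projected and separable", {
  base <- hyolingual:::tongue_baseline()
  co <- array(rep(base, each = 1), c(1, nrow(base), 3))
  ms <- marker_set(co, rownames(base), 200)
  hd <- matrix(hyolingual:::hyoid_dorsal_baseline(), 1)
  d <- tongue_dimensions(ms, hd)
  expect_equal(d$posterior_width, 22)      # lateral posterior markers at Z = +/-11
  expect_equal(d$posterior_depth, 20)      # posterior surface Y=10 vs hyoid Y=-10
  expect_equal(d$posterior_length, 17)
  expect_equal(d$tb_length, 8)             # posterolateral midpoint X=18, vallecula X=10
  # symmetric widening by delta raises width by 2*delta, leaves others fixed
  co2 <- ms$coords
  co2[1, "posterior_right", 3] <- co2[1, "posterior_right", 3] + 1.5
  co2[1, "posterior_left", 3] <- co2[1, "posterior_left", 3] - 1.5
  d2 <- tongue_dimensions(marker_set(co2, rownames(base), 200), hd)
  expect_equal(d2$posterior_width, d$posterior_width + 3)
  expect_equal(d2$posterior_length, d$posterior_length)
  expect_equal(d2$posterior_depth, d$posterior_depth)
})

test_that("programmed tongue-base length increase is recovered through the marker paths", {
  sc <- swallow_scenario(seed = 2, marker_noise_sd = 0)
  def <- generate_tongue_deformation(sc)
  ms <- marker_set(def$paths, dimnames(def$paths)[[2]], 200)
  td <- tongue_dimensions(ms, def$hyoid_dorsal)
  on <- 81; off <- 141
  expect_equal(td$tb_length[off] - td$tb_length[on], 3.61, tolerance = 1e-9)
})
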