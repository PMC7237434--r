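# one moderately sized generated scenario reused across several blocks
gen_cache <- new.env()
get_gen <- function(seed = 5, noise = 0) {
  key <- paste0("s", seed, "_n", noise)
  if (is.null(gen_cache[[key]]))
    gen_cache[[key]] <- generate_scenario(
      swallow_scenario(seed = seed, marker_noise_sd = noise))
  gen_cache[[key]]
}

test_that("generation is deterministic given the seed", {
  g1 <- generate_scenario(swallow_scenario(seed = 42))
  g2 <- generate_scenario(swallow_scenario(seed = 42))
  expect_identical(g1$markers$coords, g2$markers$coords)
  expect_identical(g1$emg$geniohyoid$raw, g2$emg$geniohyoid$raw)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_scenario(swallow_scenario(seed = 43))
  expect_false(identical(g1$markers$coords, g3$markers$coords))
})

test_that("all-zero targets produce a static constellation", {
  sc <- swallow_scenario(seed = 1, marker_noise_sd = 0,
                         hyoid_excursion = c(protraction = 0, elevation = 0),
                         retraction = c(posterior_surface = 0,
                                        posterior_deep = 0, vallecula = 0),
                         tb_length_increase = 0,
                         posterior_deep_elevation = 0,
                         volume_targets = c(pot = 0, tb = 0))
  def <- generate_tongue_deformation(sc)
  rng <- apply(def$paths, c(2, 3), function(v) diff(range(v)))
  expect_lt(max(rng), 1e-12)
  expect_equal(unname(def$achieved), c(0, 0, 0), tolerance = 1e-9)
})

test_that("volume-target search hits the requested deltas within 2 percent", {
  sc <- swallow_scenario(seed = 5, marker_noise_sd = 0)
  def <- generate_tongue_deformation(sc)
  expect_lt(abs(def$achieved[["pot"]] / 0.85 - 1), 0.02)
  expect_lt(abs(def$achieved[["tb"]] / 0.65 - 1), 0.02)
  expect_lt(abs(def$achieved[["aot"]]), 0.01)
})

test_that("a tongue-base-only volume target leaves the anterior tongue unchanged", {
  sc <- swallow_scenario(seed = 6, marker_noise_sd = 0,
                         volume_targets = c(pot = 0, tb = 0.65))
  def <- generate_tongue_deformation(sc)
  expect_gte(def$achieved[["tb"]], 0.65 * 0.98)
  expect_lte(def$achieved[["tb"]], 0.65 * 1.02)
  expect_lt(abs(def$achieved[["aot"]]), 0.01)
  expect_lt(abs(def$achieved[["pot"]]), 0.02)
})

test_that("doubling all marker coordinates scales achieved volumes eightfold", {
  sc <- swallow_scenario(seed = 7, marker_noise_sd = 0)
  def <- generate_tongue_deformation(sc)
  on <- 81
  ms1 <- marker_set(def$paths, dimnames(def$paths)[[2]], 200)
  v1 <- regional_volumes(ms1, def$hyoid_dorsal, frames = on,
                         n_ring = 150, density = 2)
  ms2 <- marker_set(def$paths * 2, dimnames(def$paths)[[2]], 200)
  v2 <- regional_volumes(ms2, def$hyoid_dorsal * 2, frames = on,
                         n_ring = 150, density = 2)
  expect_equal(unlist(v2[1, 2:4]), 8 * unlist(v1[1, 2:4]), tolerance = 1e-9)
})

test_that("noiseless generator output is recovered exactly by the kinematic pipeline", {
  gen <- get_gen(5, 0)
  tr <- gen$truth
  ps <- marker_xyz(gen$markers, "posterior_surface")[, 1]
  vx <- marker_xyz(gen$markers, "vallecula")[, 1]
  ev <- detect_tbr(ps, vx, window = c(20, 195))
  expect_equal(ev$onset, tr$onset_frame)
  expect_equal(ev$offset, tr$offset_frame)
  # programmed displacement deltas recovered to numerical precision
  expect_equal(ps[ev$offset] - ps[ev$onset],
               -tr$retraction[["posterior_surface"]], tolerance = 1e-6)
  pd <- marker_xyz(gen$markers, "posterior_deep")[, 1]
  expect_equal(pd[ev$offset] - pd[ev$onset],
               -tr$retraction[["posterior_deep"]], tolerance = 1e-6)
  # muscle deltas from the muscle module match the generator's record
  sg <- muscle_length(muscle_def("sg", c(12, 10, 12), "styloglossus_ins"),
                      gen$markers)
  expect_equal(sg[ev$offset] - sg[ev$onset],
               tr$muscle_deltas_mm[["styloglossus"]], tolerance = 1e-6)
  expect_equal(tr$muscle_deltas_mm[["styloglossus"]], -0.76, tolerance = 1e-9)
  expect_equal(tr$muscle_deltas_mm[["hyoglossus"]],
               -sqrt(4.23^2 + 2.13^2), tolerance = 1e-6)
  # hyoid excursion via the rigid-body path
  hp <- pose_series(gen$bone_refs$hyoid, gen$bones$hyoid)
  hyc <- posed_point(hp, colMeans(gen$bone_refs$hyoid))
  he <- hyoid_excursion(hyc, reference_frame = ev$onset)
  expect_equal(he$protraction[ev$offset], 4.23, tolerance = 1e-6)
  expect_equal(he$elevation[ev$offset], 2.13, tolerance = 1e-6)
  # gape recovered through pose estimation
  mp <- pose_series(gen$bone_refs$mandible, gen$bones$mandible)
  expect_lt(max(abs(gape_pitch_angle(mp) - tr$gape_deg)), 1e-9)
})

test_that("EMG bursts are time-locked to the programmed schedule", {
  gen <- get_gen(5, 0)
  for (nm in c("geniohyoid", "mylohyoid")) {
    ch <- gen$emg[[nm]]
    env <- condition_signal(ch$raw, ch$fs, hp = 30, lp = 900)
    th <- thexton_threshold(env, seed = 3)
    fl <- activity_flags(env, th$threshold)
    main <- fl$bursts[which.max(fl$bursts$offset - fl$bursts$onset), ]
    want <- ch$bursts[[1]] * env$rate
    expect_lte(abs(main$onset - want[1]), 2)
    expect_lte(abs(main$offset - want[2]), 2)
  }
})

test_that("scenario tables round trip through disk including ground truth", {
  gen <- get_gen(5, 0)
  td <- withr::local_tempdir()
  hyolingual:::write_scenario(gen, td)
  back <- read_marker_table(file.path(td, "tongue_markers.csv"), 200)
  expect_equal(back$coords, gen$markers$coords, tolerance = 1e-7)
  truth <- jsonlite::read_json(file.path(td, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$onset_frame, gen$truth$onset_frame)
  expect_equal(truth$volume_deltas_ml[["pot"]],
               gen$truth$volume_deltas_ml[["pot"]], tolerance = 1e-9)
})

test_that("precision recordings reproduce the requested noise scale", {
  pr <- generate_precision_recording(400, noise_sd = 0.07, seed = 2)
  sds <- apply(pr$coords, c(2, 3), sd)
  expect_lt(abs(mean(sds) - 0.07), 0.01)
  v <- central_velocity(marker_xyz(pr, "posterior_surface")[, 1], 200)
  b <- zero_velocity_band(v)
  expect_gt(b[2], 0)
})
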