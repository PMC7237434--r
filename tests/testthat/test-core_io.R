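test_that("marker tables read with correct shape and missing-value handling", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a_X,a_Y,a_Z,b_X,b_Y,b_Z",
               "1,2,3,4,5,6",
               "1.5,NA,3.5,4.5,5.5,6.5",
               "2,3,4,5,6,7"), tf)
  ms <- read_marker_table(tf, frame_rate = 200)
  expect_equal(dim(ms$coords), c(3L, 2L, 3L))
  expect_equal(marker_names(ms), c("a", "b"))
  expect_true(is.na(ms$coords[2, "a", 2]))
  expect_equal(ms$coords[2, "a", 1], 1.5)      # other cells of the row intact
  expect_equal(ms$coords[2, "b", ], c(X = 4.5, Y = 5.5, Z = 6.5))
})

test_that("marker table round trip is lossless to 6 decimals", {
  set.seed(42)
  co <- array(rnorm(20 * 4 * 3, sd = 20), c(20, 4, 3))
  co[7, 2, ] <- NA
  ms <- marker_set(co, c("p1", "p2", "p3", "p4"), 200)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_marker_table(ms, tf)
  back <- read_marker_table(tf, 200)
  expect_equal(back$coords, ms$coords, tolerance = 1e-7)
})

test_that("malformed marker tables raise informative errors", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a_X,a_Y,b_X,b_Y,b_Z", "1,2,3,4,5"), tf)
  expect_error(read_marker_table(tf), "a")     # names the broken marker
  tf2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), tf2)
  expect_error(read_marker_table(tf2))
})

test_that("gap interpolation is explicit, linear, and bounded", {
  co <- array(0, c(10, 1, 3))
  co[, 1, 1] <- 1:10
  co[4:5, 1, 1] <- NA        # short interior gap
  co[8:10, 1, 1] <- NA       # trailing gap stays missing
  ms <- interpolate_gaps(marker_set(co, "m", 200), max_gap = 5)
  expect_equal(ms$coords[4:5, 1, 1], c(4, 5))
  expect_true(all(is.na(ms$coords[8:10, 1, 1])))
})

test_that("OBJ writer emits v/f records and round trips through an independent parser", {
  m <- corner_tetra_mesh()
  tf <- withr::local_tempfile(fileext = ".obj")
  write_obj(m, tf)
  ln <- readLines(tf)
  expect_equal(sum(startsWith(ln, "v ")), 4L)
  expect_equal(sum(startsWith(ln, "f ")), 4L)
  # independent minimal parser
  vs <- do.call(rbind, lapply(strsplit(grep("^v ", ln, value = TRUE), " "),
                              function(x) as.numeric(x[2:4])))
  fs <- do.call(rbind, lapply(strsplit(grep("^f ", ln, value = TRUE), " "),
                              function(x) as.integer(x[2:4])))
  expect_equal(nrow(vs), nrow(m$vertices))
  expect_equal(vs, unname(m$vertices))
  expect_setequal(apply(fs, 1, function(v) paste(sort(v), collapse = "-")),
                  apply(m$faces, 1, function(v) paste(sort(v), collapse = "-")))
  # package reader agrees too
  back <- read_obj(tf)
  expect_equal(back$vertices, unname(m$vertices))
  expect_error(write_obj(structure(list(vertices = matrix(0, 0, 3),
                                        faces = matrix(0L, 0, 3)),
                                   class = "tri_mesh"), tf))
})

test_that("anatomical frame is canonical on canonical landmarks and exact for coplanar palates", {
  # first three landmarks wind counterclockwise viewed from superior (+Y)
  palate <- rbind(c(-5, 0, 4), c(5, 0, 4), c(5, 0, -4), c(-5, 0, -4))
  palate <- sweep(palate, 2, colMeans(palate))    # zero centroid
  midline <- rbind(c(-10, 0, 0), c(10, 0, 0))
  fr <- build_anatomical_frame(palate, midline)
  expect_equal(fr$origin, c(0, 0, 0))
  expect_equal(fr$axes, diag(3), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(max(abs(to_frame(palate, fr)[, 2])), 0, tolerance = 1e-9)
})

test_that("anatomical frame construction is equivariant under rigid transforms", {
  set.seed(7)
  palate <- cbind(rnorm(6, sd = 5), rnorm(6, sd = 0.3), rnorm(6, sd = 4))
  midline <- rbind(c(-8, 0.1, 0.2), c(9, -0.2, 0.1))
  f0 <- build_anatomical_frame(palate, midline)
  for (i in 1:5) {
    R <- random_rotation(); tr <- rnorm(3, sd = 10)
    f1 <- build_anatomical_frame(sweep(palate %*% t(R), 2, tr, `+`),
                                 sweep(midline %*% t(R), 2, tr, `+`))
    expect_equal(f1$axes, R %*% f0$axes, tolerance = 1e-9)
    expect_equal(f1$origin, as.numeric(R %*% f0$origin + tr), tolerance = 1e-9)
  }
  expect_error(build_anatomical_frame(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                                      midline), "collinear")
})

test_that("config round trips through YAML and validates parameters", {
  cfg <- pipeline_config(alpha = 4, n_ring = 150, seed = 9L)
  tf <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, tf)
  back <- read_config(tf)
  expect_equal(back$alpha, 4)
  expect_equal(back$n_ring, 150L)
  expect_equal(back$seed, 9L)
  expect_error(pipeline_config(alpha = -1))
})
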