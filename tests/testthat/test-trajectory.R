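make_xyz <- function(frames, path) {
  lines <- unlist(lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    c(nrow(fr), paste("frame", i),
      sprintf("%s %.6f %.6f %.6f", fr$element, fr$x, fr$y, fr$z))
  }))
  writeLines(lines, path)
  path
}

test_that("multi-frame XYZ files round-trip through the reader", {
  fr <- tibble::tibble(element = c("N", "N", "C"),
                       x = c(0, 1, 2), y = c(0, 0, 1), z = c(0, 0.5, 1.5))
  path <- withr::local_tempfile(fileext = ".xyz")
  make_xyz(list(fr, dplyr::mutate(fr, z = z + 1)), path)
  tr <- read_xyz_trajectory(path)
  expect_equal(unique(tr$frame), c(1, 2))
  expect_equal(tr$z[tr$frame == 2], fr$z + 1)
  expect_equal(tr$element[1:3], fr$element)
})

test_that("pose reduction recovers the limiting tilt geometries", {
  # planar chromophore in the xy-plane, N-N vector in-plane: tilt 0
  fr <- tibble::tibble(frame = 1, atom = 1:4, element = "X",
                       x = c(0, 1, 0, 0), y = c(0, 0, 1, 0),
                       z = c(5, 5, 5, 0))
  ps <- pose_series(fr, chromophore_atoms = 1:3, masses = c(1, 1, 1),
                    center_atoms = 4, ref = ref_spec(c(2, 1), c(1, -1)))
  expect_equal(ps$tilt_deg, 0)
  expect_equal(ps$depth, 5)

  # reference vector along z: tilt 90
  fr2 <- dplyr::mutate(fr, x = c(0, 0, 0, 0), z = c(5, 6, 5, 0))
  ps2 <- pose_series(fr2, 1:3, c(1, 1, 1), 4, ref_spec(c(2, 1), c(1, -1)))
  expect_equal(ps2$tilt_deg, 90)
  expect_error(pose_series(fr, integer(0), numeric(0), 4,
                           ref_spec(c(2, 1), c(1, -1))), "empty")
})

test_that("pose observables have the membrane-frame invariances", {
  set.seed(31)
  fr <- tibble::tibble(frame = 1, atom = 1:5, element = "X",
                       x = rnorm(5), y = rnorm(5), z = rnorm(5) + c(rep(8, 4), 0))
  ref <- ref_spec(c(2, 1), c(1, -1))
  base <- pose_series(fr, 1:4, rep(1, 4), 5, ref)

  R <- rotation_about_z(73)
  xyz <- as.matrix(fr[, c("x", "y", "z")]) %*% t(R)
  rot <- pose_series(dplyr::mutate(fr, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
                     1:4, rep(1, 4), 5, ref)
  expect_equal(rot$tilt_deg, base$tilt_deg, tolerance = 1e-10)
  expect_equal(rot$depth, base$depth, tolerance = 1e-10)

  refl <- pose_series(dplyr::mutate(fr, z = -z), 1:4, rep(1, 4), 5, ref)
  expect_equal(refl$tilt_deg, base$tilt_deg, tolerance = 1e-10)
  expect_equal(refl$depth, base$depth, tolerance = 1e-10)

  shifted <- pose_series(dplyr::mutate(fr, x = x + 40, y = y - 13),
                         1:4, rep(1, 4), 5, ref)
  expect_equal(shifted$depth, base$depth, tolerance = 1e-10)
})

test_that("trajectory means pool frames and honor exclusions", {
  s1 <- tibble::tibble(depth = rep(10, 50), tilt_deg = rep(5, 50))
  s2 <- tibble::tibble(depth = rep(20, 50), tilt_deg = rep(15, 50))
  tm <- trajectory_means(list(a = s1, b = s2))
  expect_equal(tm$per_trajectory$depth_mean, c(10, 20))
  expect_equal(tm$pooled$depth_mean, 15)

  tm2 <- trajectory_means(list(a = s1, b = s2), exclude = "b")
  expect_equal(tm2$pooled$depth_mean, 10)
  expect_true(tm2$per_trajectory$excluded[2])
  expect_error(trajectory_means(list(a = s1), exclude = TRUE), "excluded")
})

test_that("pose means are recovered from a seeded synthetic trajectory", {
  tr <- synth_pose_trajectory(4000, seed = 101, depth_mean = 13.3,
                              depth_sd = 1, tilt_mean = 11.7, tilt_sd = 5)
  # AR(1) with rho = 0.95 inflates the standard error by sqrt((1+rho)/(1-rho))
  infl <- sqrt(1.95 / 0.05)
  expect_lt(abs(mean(tr$depth) - 13.3), 3 * infl * 1 / sqrt(4000))
  expect_lt(abs(mean(tr$tilt_deg) - 11.7), 3 * infl * 5 / sqrt(4000) + 0.5)
})

test_that("bimodal insertion depths average between the modes", {
  # fast mean reversion and rare switching so each mode is well resolved
  tr <- synth_pose_trajectory(6000, seed = 202, depth_sd = 1, rho = 0.5,
                              depth_modes = c(17, 30), p_switch = 0.005)
  expect_gt(mean(tr$depth), 17)
  expect_lt(mean(tr$depth), 30)
  expect_equal(sort(unique(tr$mode)), c(1, 2))
  # per-mode means sit at the configured modes
  expect_equal(mean(tr$depth[tr$mode == 1]), 17, tolerance = 0.05)
  expect_equal(mean(tr$depth[tr$mode == 2]), 30, tolerance = 0.05)
})

test_that("detachment screening distinguishes bound, leaving and borderline runs", {
  bound <- tibble::tibble(depth = runif(100, 10, 30))
  expect_true(detachment_screen(bound)$keep)

  leaving <- tibble::tibble(depth = seq(10, 120, length.out = 100))
  expect_false(detachment_screen(leaving)$keep)

  borderline <- tibble::tibble(depth = c(rep(20, 90), rep(45, 10)))
  sc <- detachment_screen(borderline, threshold = 40, min_fraction = 0.25)
  expect_true(sc$keep)
  expect_equal(sc$fraction_beyond, 0.1)
})

test_that("pose tables round-trip through the delimited writer", {
  tr <- synth_pose_trajectory(20, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pose_table(tr, path)
  back <- read_pose_table(path)
  expect_equal(back$depth, tr$depth, tolerance = 1e-9)
})
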