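test_that("the golden-rule rate reproduces the published per-state rates from printed factors", {
  tab <- table1_states()
  k <- fret_rate(tab$V2_printed, tab$overlap_cm)
  expect_equal(k, tab$k_printed, tolerance = 0.02)
  expect_equal(fret_rate(5.80e-46, 0), 0)
  expect_error(fret_rate(-1e-46, 1e-4), "non-negative")
})

test_that("the two-step assembly reproduces the published totals", {
  geo <- table1_geometry()
  bd <- two_step_rates(table1_states(), geo$donor_debye, geo$donor_tilt_deg,
                       geo$r_angstrom, geo$eta)
  expect_s3_class(bd, "fret_breakdown")
  expect_equal(bd$V2, table1_states()$V2_printed, tolerance = 0.10)
  expect_equal(bd$V_cm, table1_states()$V_cm_printed, tolerance = 0.05)
  g <- glance(bd)
  expect_equal(g$k_total, geo$k_total, tolerance = 0.10)
  expect_equal(g$tau_total_ns, geo$tau_total_ns, tolerance = 0.10)
  expect_equal(attr(bd, "k_total"), sum(bd$k_fret))  # totals by exact summation
})

test_that("two-step rates are additive, linear in the overlap, and guard inputs", {
  st <- table1_states()[2, ]
  one <- two_step_rates(st, 12.3, 11.7, 33.4)
  two <- two_step_rates(dplyr::bind_rows(st, st), 12.3, 11.7, 33.4)
  expect_equal(attr(two, "k_total"), 2 * attr(one, "k_total"), tolerance = 1e-12)

  zero <- two_step_rates(dplyr::mutate(st, overlap_cm = 0), 12.3, 11.7, 33.4)
  expect_equal(attr(zero, "k_total"), 0)

  doubled <- two_step_rates(dplyr::mutate(st, overlap_cm = overlap_cm * 2),
                            12.3, 11.7, 33.4)
  expect_equal(attr(doubled, "k_total"), 2 * attr(one, "k_total"),
               tolerance = 1e-12)

  expect_error(
    two_step_rates(dplyr::mutate(st, overlap_cm = NA), 12.3, 11.7, 33.4),
    "S6")
})

test_that("a single identical pair makes the one-step and two-step routes coincide", {
  phi_d <- 11.7; phi_a <- 29.6
  don <- snapshot_from_frame(1, depth = 13.3, strength_debye = 12.3,
                             tilt_deg = phi_d, energy_ev = 2.2)
  acc <- snapshot_from_frame(1, depth = 20.1, strength_debye = 3.2,
                             tilt_deg = phi_a, energy_ev = 2.3, state = "S8")
  os <- one_step_rates(don, acc, fwhm_d_ev = 0.05, fwhm_a_ev = 0.2)
  j_pair <- overlap_gaussian_pair(2.2, 0.05, 2.3, 0.2)
  ts <- two_step_rates(
    tibble::tibble(state = "S8", strength_debye = 3.2, tilt_deg = phi_a,
                   overlap_cm = j_pair),
    donor_debye = 12.3, donor_tilt_deg = phi_d, r_angstrom = 33.4)
  expect_equal(attr(os, "k_total"), attr(ts, "k_total"), tolerance = 1e-9)
  expect_equal(os$V2, ts$V2, tolerance = 1e-9)
})

test_that("a 1x1 pair equals the hand-composed coupling-overlap-rate chain", {
  don <- snapshot_from_frame(1, 10, 12.3, 0, 2.2)
  acc <- snapshot_from_frame(1, 15, 3.2, 0, 2.25, state = "S1")
  os <- one_step_rates(don, acc)
  k <- fret_constants()
  pref <- ((12.3 * k$debye) * (3.2 * k$debye) /
             (4 * pi * k$eps0 * 1.478^2 * (25e-10)^3))^2
  expected <- fret_rate(pref * kappa2_mean_closed(0, 0),
                        overlap_gaussian_pair(2.2, 0.05, 2.25, 0.2))
  expect_equal(attr(os, "k_total"), expected, tolerance = 1e-6)
})

test_that("identical snapshots give the single-pair rate; depth scaling follows r^-6", {
  don1 <- snapshot_from_frame(1, 13, 12.3, 10, 2.2)
  don <- dplyr::mutate(don1[rep(1, 5), ], frame = 1:5)
  acc1 <- snapshot_from_frame(1, 20, 3.2, 30, 2.3, state = "S1")
  acc <- dplyr::mutate(acc1[rep(1, 4), ], frame = 1:4)
  os_many <- one_step_rates(don, acc)
  os_one <- one_step_rates(don1, acc1)
  expect_equal(attr(os_many, "k_total"), attr(os_one, "k_total"),
               tolerance = 1e-12)

  s <- 1.3
  os_scaled <- one_step_rates(dplyr::mutate(don, depth = depth * s),
                              dplyr::mutate(acc, depth = depth * s))
  expect_equal(attr(os_scaled, "k_total"),
               attr(os_many, "k_total") * s^-6, tolerance = 1e-10)
})

test_that("heavy-tailed distances make the mean rate exceed the rate at mean distance", {
  set.seed(17)
  nd <- 20; na <- 20
  don <- dplyr::bind_rows(lapply(1:nd, function(i) {
    snapshot_from_frame(i, depth = 8 + rlnorm(1, 1, 0.8), strength_debye = 12.3,
                        tilt_deg = 10, energy_ev = 2.2)
  }))
  acc <- dplyr::bind_rows(lapply(1:na, function(i) {
    snapshot_from_frame(i, depth = 10 + rlnorm(1, 1, 0.8), strength_debye = 3.2,
                        tilt_deg = 30, energy_ev = 2.3, state = "S1")
  }))
  os <- one_step_rates(don, acc)
  os_mean_d <- one_step_rates(dplyr::mutate(don, depth = mean(don$depth)),
                              dplyr::mutate(acc, depth = mean(acc$depth)))
  expect_gt(attr(os, "k_total"), attr(os_mean_d, "k_total"))
})

test_that("one-step per-state means are means of per-pair values, not rates of means", {
  set.seed(23)
  don <- dplyr::bind_rows(lapply(1:6, function(i) {
    snapshot_from_frame(i, depth = 8 + rlnorm(1, 1, 0.6), 12.3, 10, 2.2)
  }))
  acc <- dplyr::bind_rows(lapply(1:6, function(i) {
    d <- 10 + rlnorm(1, 1, 0.6)
    # deeper snapshots sit in a less polar environment: couple the vertical
    # energy to the depth so overlap and coupling co-vary across pairs
    snapshot_from_frame(i, depth = d, 3.2, 30, 2.25 + 0.02 * (d - 12),
                        state = "S1")
  }))
  os <- one_step_rates(don, acc)
  rate_of_means <- fret_rate(os$V2, os$overlap_cm)
  expect_gt(os$k_fret, rate_of_means)  # Jensen: distances vary across pairs
  # totals: mean over pairs of summed states == sum of per-state mean rates
  expect_equal(attr(os, "k_total"), sum(os$k_fret), tolerance = 1e-12)
})

test_that("one-step input contracts are enforced", {
  don <- snapshot_from_frame(1, 10, 12.3, 0, 2.2)
  acc <- snapshot_from_frame(1, 15, 3.2, 0, 2.25, state = "S1")
  expect_error(one_step_rates(don, acc, states = c("S1", "S2")), "S2")
  don2 <- dplyr::bind_rows(don, don)  # duplicate frame id
  expect_error(one_step_rates(don2, acc), "one emissive")
})

test_that("breakdown tidiers expose per-state rows and totals", {
  bd <- two_step_rates(table1_states(), 12.3, 11.7, 33.4)
  td <- tidy(bd)
  expect_false(inherits(td, "fret_breakdown"))
  expect_equal(nrow(td), 4)
  g <- glance(bd)
  expect_equal(g$n_states, 4)
  expect_equal(g$k_total * g$tau_total_ns * 1e-9, 1, tolerance = 1e-12)
  p <- autoplot(bd)
  expect_s3_class(p, "ggplot")
})
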