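# Shared fixtures, built in code.

# Published two-step per-state inputs and results for the membrane donor
# (perylene diimide emitter, 12.3 D at 11.7 deg) and the ruthenium
# tris-bipyridine acceptor: strengths/tilts per state, printed couplings,
# overlaps, rates and lifetimes.
table1_states <- function() {
  tibble::tibble(
    state = c("S5", "S6", "S7", "S8"),
    strength_debye = c(1.2, 2.5, 3.2, 3.2),
    tilt_deg = c(49.6, 29.6, 49.6, 29.6),
    overlap_cm = c(2.12e-4, 1.44e-4, 8.00e-5, 8.00e-5),
    V2_printed = c(9.90e-47, 5.80e-46, 7.15e-46, 9.76e-46),
    V_cm_printed = c(0.501, 1.21, 1.35, 1.57),
    k_printed = c(6.28e7, 2.49e8, 1.72e8, 2.34e8),
    tau_ns_printed = c(15.9, 4.01, 5.82, 4.27)
  )
}

table1_geometry <- function() {
  list(donor_debye = 12.3, donor_tilt_deg = 11.7, r_angstrom = 33.4,
       eta = 1.478, k_total = 7.18e8, tau_total_ns = 1.39)
}

# convert a dipole magnitude in Debye to au
debye_to_au <- function(mu_debye) mu_debye / fret_constants()$debye_per_au

# a one-row snapshot table holding a membrane-frame dipole (tilt in the
# xz-plane) expressed in au components, as the one-step reader expects
snapshot_from_frame <- function(frame, depth, strength_debye, tilt_deg,
                                energy_ev, state = NULL) {
  mu_au <- debye_to_au(strength_debye)
  phi <- tilt_deg * pi / 180
  out <- tibble::tibble(frame = frame, depth = depth, energy_ev = energy_ev,
                        mx = mu_au * cos(phi), my = 0, mz = mu_au * sin(phi))
  if (!is.null(state)) out <- dplyr::mutate(out, state = state, .after = "depth")
  out
}

# exactly symmetric bipyridine-like nitrogen cage: first two N on the C2
# axis (z), remaining four in the xy-plane
bipy_cage <- function() {
  tibble::tibble(
    x = c(0, 0, 1, 1, -1, -1),
    y = c(0, 0, 1, -1, 1, -1),
    z = c(1, 2, 0, 0, 0, 0)
  )
}

rotation_about_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), nrow = 3)
}
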