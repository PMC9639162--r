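#' Synthetic inputs for every stage of the pipeline
#'
#' Statistical scaffolding that emulates the upstream producers — conformer
#' ensembles from quantum chemistry, snapshot sets from embedded-environment
#' calculations, pose time series from classical trajectories — with
#' controllable structure and mandatory seeds. It makes no attempt at
#' physically realistic dynamics; every distribution is chosen so that the
#' statistical features the pipeline keys on (weight concentration,
#' orientational order or disorder, insertion-depth modes) can be dialed in
#' exactly and recovered by the analysis code.
#'
#' `synth_conformer_ensemble()` draws relative energies as a cumulative sum
#' of exponential gaps (so a few low-energy conformers dominate the Boltzmann
#' weights), and transition dipoles as a base orientation perturbed by a
#' small rotation about a random axis perpendicular to it.
#'
#' @param n ensemble size
#' @param seed integer seed (mandatory; no silent global randomness)
#' @param base_tdm base transition-dipole direction (any nonzero 3-vector)
#' @param angle_sd_deg angular noise, degrees
#' @param strength_mean_au2,strength_sd_au2 dipole strength distribution, au²
#' @param energy_gap_kjmol mean gap between energy-ordered conformers, kJ/mol
#'   (default 4 kJ/mol: the three most stable conformers carry essentially
#'   all (>=95%) of the Boltzmann weight at 298 K)
#' @param energy_ev_mean,energy_ev_sd vertical excitation energy, eV
#' @return tibble: `id`, `rel_energy` (kJ/mol), `energy_ev`,
#'   `strength_au2`, `mx`, `my`, `mz` (au; |mu|² = strength)
#' @export
#' @examples
#' ens <- synth_conformer_ensemble(92, seed = 7)
#' head(weight_conformers(ens))
synth_conformer_ensemble <- function(n, seed, base_tdm = c(1, 0, 0),
                                     angle_sd_deg = 5,
                                     strength_mean_au2 = 23.8,
                                     strength_sd_au2 = 1,
                                     energy_gap_kjmol = 4,
                                     energy_ev_mean = 2.3,
                                     energy_ev_sd = 0.05) {
  stopifnot(n >= 1, angle_sd_deg >= 0, strength_sd_au2 >= 0)
  withr::with_seed(seed, {
    rel_e <- cumsum(c(0, stats::rexp(n - 1, rate = 1 / energy_gap_kjmol)))
    strength <- pmax(1e-6, stats::rnorm(n, strength_mean_au2, strength_sd_au2))
    dirs <- t(vapply(seq_len(n),
                     function(i) perturb_direction(base_tdm, angle_sd_deg),
                     numeric(3)))
    tibble::tibble(
      id = sprintf("conf%03d", seq_len(n)),
      rel_energy = rel_e,
      energy_ev = stats::rnorm(n, energy_ev_mean, energy_ev_sd),
      strength_au2 = strength,
      mx = dirs[, 1] * sqrt(strength),
      my = dirs[, 2] * sqrt(strength),
      mz = dirs[, 3] * sqrt(strength)
    )
  })
}

# rotate v by an angle drawn from N(0, sd_deg) about a uniformly random axis
# perpendicular to v: exactly controllable angular noise
perturb_direction <- function(v, sd_deg) {
  u <- v / sqrt(sum(v^2))
  if (sd_deg == 0) return(u)
  # random perpendicular axis
  w <- stats::rnorm(3)
  w <- w - sum(w * u) * u
  w <- w / sqrt(sum(w^2))
  ang <- stats::rnorm(1, 0, sd_deg) * pi / 180
  u * cos(ang) + sin(ang) * w  # Rodrigues, axis perpendicular to u
}

#' @rdname synth_conformer_ensemble
#'
#' @description
#' `synth_snapshot_set()` builds per-snapshot records for the one-step
#' protocol: insertion depths, per-state vertical energies, and transition
#' dipole vectors whose orientational order is switchable between `aligned`
#' (all dipoles near a base direction: step-like sorted-cos² diagnostics),
#' `isotropic` (uniform on the sphere: near-linear diagnostics) and
#' `mixture` (a 50/50 split over two orthogonal directions: sigmoid
#' diagnostics). When `depth_min` is given, depths are folded above it and
#' the smallest draw is pinned to `depth_min`, so the minimum is attained
#' exactly — the contract the closest-approach checks rely on.
#'
#' @param role `"donor"` (one emissive transition per frame, energies uniform
#'   over `energy_window_ev`) or `"acceptor"` (one record per frame and state)
#' @param depth_mean,depth_sd insertion depth distribution, Å
#' @param depth_min optional hard minimum depth, Å
#' @param energy_window_ev donor emission energy window, eV (default 2.0–2.4)
#' @param states acceptor state labels
#' @param state_energy_ev per-state mean vertical energies, eV
#' @param state_energy_sd_ev per-state energy spread, eV
#' @param orientation `"aligned"`, `"isotropic"` or `"mixture"`
#' @export
synth_snapshot_set <- function(n, seed, role = c("donor", "acceptor"),
                               depth_mean = 13.3, depth_sd = 1,
                               depth_min = NULL,
                               energy_window_ev = c(2.0, 2.4),
                               states = paste0("S", 1:10),
                               state_energy_ev = seq(1.9, 2.8, length.out = 10),
                               state_energy_sd_ev = 0.05,
                               strength_mean_au2 = 10,
                               strength_sd_au2 = 2,
                               base_tdm = c(1, 0, 0),
                               angle_sd_deg = 5,
                               orientation = c("aligned", "isotropic", "mixture")) {
  role <- match.arg(role)
  orientation <- match.arg(orientation)
  withr::with_seed(seed, {
    depth <- stats::rnorm(n, depth_mean, depth_sd)
    if (!is.null(depth_min)) {
      depth <- depth_min + abs(depth - depth_min)
      depth[which.min(depth)] <- depth_min
    } else {
      depth <- abs(depth)
    }
    if (role == "donor") {
      strength <- pmax(1e-6, stats::rnorm(n, strength_mean_au2, strength_sd_au2))
      dirs <- draw_directions(n, orientation, base_tdm, angle_sd_deg)
      tibble::tibble(
        frame = seq_len(n), depth = depth,
        energy_ev = stats::runif(n, energy_window_ev[1], energy_window_ev[2]),
        mx = dirs[, 1] * sqrt(strength),
        my = dirs[, 2] * sqrt(strength),
        mz = dirs[, 3] * sqrt(strength)
      )
    } else {
      stopifnot(length(state_energy_ev) == length(states))
      grid <- tidyr::crossing(frame = seq_len(n), state_i = seq_along(states))
      m <- nrow(grid)
      strength <- pmax(1e-6, stats::rnorm(m, strength_mean_au2, strength_sd_au2))
      dirs <- draw_directions(m, orientation, base_tdm, angle_sd_deg)
      tibble::tibble(
        frame = grid$frame,
        depth = depth[grid$frame],
        state = states[grid$state_i],
        energy_ev = stats::rnorm(m, state_energy_ev[grid$state_i],
                                 state_energy_sd_ev),
        mx = dirs[, 1] * sqrt(strength),
        my = dirs[, 2] * sqrt(strength),
        mz = dirs[, 3] * sqrt(strength)
      )
    }
  })
}

draw_directions <- function(n, orientation, base_tdm, angle_sd_deg) {
  switch(orientation,
    aligned = t(vapply(seq_len(n),
                       function(i) perturb_direction(base_tdm, angle_sd_deg),
                       numeric(3))),
    isotropic = random_unit_vectors(n),
    mixture = {
      u <- base_tdm / sqrt(sum(base_tdm^2))
      # an orthogonal partner direction
      w <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      w <- w - sum(w * u) * u
      w <- w / sqrt(sum(w^2))
      pick <- stats::runif(n) < 0.5
      t(vapply(seq_len(n), function(i) {
        perturb_direction(if (pick[i]) u else w, angle_sd_deg)
      }, numeric(3)))
    })
}

#' @rdname synth_conformer_ensemble
#'
#' @description
#' `synth_pose_trajectory()` generates mean-reverting (AR(1), i.e.
#' discretized Ornstein–Uhlenbeck) depth and tilt series around configured
#' means, with an optional two-state Markov switch between two insertion
#' depths emulating a chromophore that visits an inner and an outer binding
#' mode.
#'
#' @param n_frames series length
#' @param tilt_mean,tilt_sd tilt distribution, degrees
#' @param rho AR(1) autocorrelation (stationary sd equals the configured sd)
#' @param depth_modes optional length-2 depth means for two-mode switching
#' @param p_switch per-frame mode-switch probability
#' @param time_step_ns frame spacing, ns
#' @export
synth_pose_trajectory <- function(n_frames, seed, depth_mean = 13.3,
                                  depth_sd = 1, tilt_mean = 11.7,
                                  tilt_sd = 5, rho = 0.95,
                                  depth_modes = NULL, p_switch = 0.01,
                                  time_step_ns = 0.1) {
  stopifnot(n_frames >= 1, depth_sd >= 0, tilt_sd >= 0, rho >= 0, rho < 1)
  withr::with_seed(seed, {
    mode <- if (is.null(depth_modes)) rep(1L, n_frames) else {
      m <- integer(n_frames); m[1] <- 1L
      flips <- stats::runif(n_frames) < p_switch
      for (t in seq_len(n_frames)[-1]) {
        m[t] <- if (flips[t]) 3L - m[t - 1] else m[t - 1]
      }
      m
    }
    d_mu <- if (is.null(depth_modes)) rep(depth_mean, n_frames)
            else depth_modes[mode]
    depth <- ar1_series(n_frames, d_mu, depth_sd, rho)
    tilt <- ar1_series(n_frames, rep(tilt_mean, n_frames), tilt_sd, rho)
    tibble::tibble(
      frame = seq_len(n_frames),
      time_ns = (seq_len(n_frames) - 1) * time_step_ns,
      depth = abs(depth),
      tilt_deg = pmin(90, abs(tilt)),
      mode = mode
    )
  })
}

# AR(1) with exactly the stationary sd `s` around a (possibly time-varying)
# mean; x1 drawn from the stationary distribution
ar1_series <- function(n, mu, s, rho) {
  if (s == 0) return(mu)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, mu[1], s)
  innov <- stats::rnorm(n, 0, s * sqrt(1 - rho^2))
  for (t in seq_len(n)[-1]) {
    x[t] <- mu[t] + rho * (x[t - 1] - mu[t]) + innov[t]
  }
  x
}
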