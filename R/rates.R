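#' Golden-rule FRET rate from squared coupling and spectral overlap
#'
#' k_FRET = (2 pi / hbar) · |V_DA|² · J / (h c), with |V_DA|² in J², the
#' overlap J in cm, and h c in J·cm so that J/(hc) converts the overlap into
#' a density of final states per unit energy. Vectorized.
#'
#' @param V2 squared coupling |V_DA|² in J² (kg² m⁴ s⁻⁴), >= 0
#' @param overlap_cm spectral overlap J in cm, >= 0
#' @return rate in s⁻¹
#' @export
#' @examples
#' fret_rate(5.80e-46, 1.44e-4)  # ~2.5e8 s^-1
fret_rate <- function(V2, overlap_cm) {
  if (any(V2 < 0) || any(overlap_cm < 0)) {
    stop("coupling and overlap must be non-negative", call. = FALSE)
  }
  (2 * pi / .k$hbar) * V2 * overlap_cm / .k$hc_Jcm
}

new_fret_breakdown <- function(per_state, protocol, n_pairs = NA_integer_) {
  out <- tibble::as_tibble(per_state)
  class(out) <- c("fret_breakdown", class(out))
  attr(out, "protocol") <- protocol
  attr(out, "k_total") <- sum(per_state$k_fret)
  attr(out, "n_pairs") <- n_pairs
  out
}

#' Two-step FRET rate assembly
#'
#' The two-step protocol combines ensemble photophysics computed in implicit
#' solvent (per-state dipole strengths and spectral overlaps) with membrane
#' geometry statistics from classical trajectories (mean insertion depths and
#' dipole tilts). For each acceptor state the azimuthally averaged squared
#' coupling is computed from the membrane-frame dipoles and combined with the
#' state's overlap via [fret_rate()]; the total rate is the sum over states.
#'
#' @param states data frame with one row per acceptor state and columns
#'   `state`, `strength_debye`, `tilt_deg`, `overlap_cm`
#' @param donor_debye donor emissive dipole magnitude, Debye
#' @param donor_tilt_deg donor dipole tilt to the membrane plane, degrees
#' @param r_angstrom donor–acceptor separation along the membrane normal, Å
#'   (sum of the two mean insertion depths)
#' @param eta medium refractive index (default 1.478, DPPC monolayer)
#' @param azimuth_step_deg azimuth grid step for the rotational average
#' @return a `fret_breakdown`: per-state tibble with columns `state`, `V2`
#'   (J²), `V_cm` (cm⁻¹), `overlap_cm`, `k_fret` (s⁻¹), `tau_ns`; attributes
#'   `k_total` and `protocol`. See [tidy.fret_breakdown()] and
#'   [glance.fret_breakdown()].
#' @export
#' @examples
#' states <- tibble::tibble(
#'   state = c("S5", "S6", "S7", "S8"),
#'   strength_debye = c(1.2, 2.5, 3.2, 3.2),
#'   tilt_deg = c(49.6, 29.6, 49.6, 29.6),
#'   overlap_cm = c(2.12e-4, 1.44e-4, 8.00e-5, 8.00e-5))
#' two_step_rates(states, donor_debye = 12.3, donor_tilt_deg = 11.7,
#'                r_angstrom = 33.4)
two_step_rates <- function(states, donor_debye, donor_tilt_deg, r_angstrom,
                           eta = 1.478, azimuth_step_deg = 1) {
  stopifnot(nrow(states) >= 1)
  missing_ov <- is.na(states$overlap_cm)
  if (any(missing_ov)) {
    stop("missing spectral overlap for state(s): ",
         paste(states$state[missing_ov], collapse = ", "), call. = FALSE)
  }
  per_state <- dplyr::mutate(
    tibble::as_tibble(states),
    V2 = purrr::map2_dbl(.data$strength_debye, .data$tilt_deg,
      ~rotational_average_V2(donor_debye, donor_tilt_deg, .x, .y,
                             r_angstrom, eta, azimuth_step_deg)),
    V_cm = coupling_to_wavenumber(sqrt(.data$V2)),
    k_fret = fret_rate(.data$V2, .data$overlap_cm),
    tau_ns = 1e9 / .data$k_fret
  )
  new_fret_breakdown(
    per_state[, c("state", "strength_debye", "tilt_deg", "V2", "V_cm",
                  "overlap_cm", "k_fret", "tau_ns")],
    protocol = "two-step")
}

#' One-step FRET rate over donor × acceptor snapshot pairs
#'
#' In the one-step protocol every quantity is taken per snapshot of the
#' chromophore inside the explicit membrane: the transition dipole vectors,
#' the vertical excitation energies, and the insertion depth. For every pair
#' of one donor snapshot and one acceptor snapshot (the full Cartesian
#' product), the interchromophoric distance is the sum of the two depths
#' along the membrane normal, the azimuthal rotation of the acceptor dipoles
#' about the normal is sampled on a uniform grid, the per-state overlap is
#' the closed-form Gaussian pair overlap of the two vertical energies, and
#' the pair's rate is the sum of the per-state golden-rule rates. The overall
#' rate is the arithmetic mean of the per-pair rates — not the rate evaluated
#' at mean couplings and overlaps, which would miss close-approach pairs.
#'
#' @param donor_snaps data frame of donor snapshots: columns `frame`,
#'   `depth` (Å), `energy_ev`, `mx`, `my`, `mz` (transition dipole, au);
#'   exactly one emissive transition per frame
#' @param acceptor_snaps data frame of acceptor snapshots: columns `frame`,
#'   `depth`, `state`, `energy_ev`, `mx`, `my`, `mz`
#' @param states acceptor state labels to include (default: all present)
#' @param fwhm_d_ev,fwhm_a_ev Gaussian line widths for donor emission and
#'   acceptor absorption, eV (defaults 0.05 and 0.2)
#' @param eta medium refractive index
#' @param azimuth_step_deg azimuth grid step, degrees
#' @return a `fret_breakdown` whose per-state rows hold the means over all
#'   pairs of |V_DA|², J and k (state-resolved diagnostics); attributes
#'   `k_total` (mean over pairs of the summed-state rate), `n_pairs`,
#'   `pair_rates` (tibble of per-pair total rates) and `protocol`.
#' @export
one_step_rates <- function(donor_snaps, acceptor_snaps, states = NULL,
                           fwhm_d_ev = 0.05, fwhm_a_ev = 0.2, eta = 1.478,
                           azimuth_step_deg = 1) {
  stopifnot(nrow(donor_snaps) >= 1, nrow(acceptor_snaps) >= 1)
  if (anyDuplicated(donor_snaps$frame)) {
    stop("donor snapshots must carry exactly one emissive transition per frame",
         call. = FALSE)
  }
  if (is.null(states)) states <- sort(unique(acceptor_snaps$state))
  acc <- dplyr::filter(tibble::as_tibble(acceptor_snaps), .data$state %in% states)
  state_by_frame <- split(acc$state, acc$frame)
  missing <- unique(unlist(lapply(state_by_frame, function(s) setdiff(states, s))))
  if (length(missing)) {
    stop("acceptor snapshot(s) lack state(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  don <- tibble::as_tibble(donor_snaps)

  # Cartesian product, expanded per acceptor state
  pairs <- tidyr::crossing(d_idx = seq_len(nrow(don)),
                           a_idx = seq_len(nrow(acc)))
  dd <- don[pairs$d_idx, ]
  aa <- acc[pairs$a_idx, ]

  mu_d_mat <- as.matrix(dd[, c("mx", "my", "mz")])
  mu_a_mat <- as.matrix(aa[, c("mx", "my", "mz")])
  nd <- sqrt(rowSums(mu_d_mat^2))
  na_ <- sqrt(rowSums(mu_a_mat^2))
  if (any(nd == 0) || any(na_ == 0)) {
    stop("zero transition dipole in snapshot set", call. = FALSE)
  }
  k2 <- azimuthal_kappa2_mean(mu_d_mat / nd, mu_a_mat / na_, azimuth_step_deg)

  # strengths |mu|^2 in au^2 -> SI; prefactor of the screened dipole coupling
  mu2_si <- dipole_strength_au2_to_SI(nd^2) * dipole_strength_au2_to_SI(na_^2)
  r_m <- (dd$depth + aa$depth) * 1e-10
  V2 <- k2 * mu2_si / (4 * pi * .k$eps0 * eta^2 * r_m^3)^2
  Jov <- overlap_gaussian_pair(dd$energy_ev, fwhm_d_ev, aa$energy_ev, fwhm_a_ev)
  k_i <- fret_rate(V2, Jov)

  res <- tibble::tibble(d_frame = dd$frame, a_frame = aa$frame,
                        state = aa$state, V2 = V2, overlap_cm = Jov,
                        k_fret = k_i)
  pair_rates <- dplyr::summarise(dplyr::group_by(res, .data$d_frame, .data$a_frame),
                                 k_pair = sum(.data$k_fret), .groups = "drop")
  per_state <- dplyr::summarise(
    dplyr::group_by(res, .data$state),
    V2 = mean(.data$V2),
    overlap_cm = mean(.data$overlap_cm),
    k_fret = mean(.data$k_fret),
    .groups = "drop")
  per_state <- dplyr::mutate(per_state,
                             V_cm = coupling_to_wavenumber(sqrt(.data$V2)),
                             tau_ns = 1e9 / .data$k_fret)
  out <- new_fret_breakdown(
    per_state[, c("state", "V2", "V_cm", "overlap_cm", "k_fret", "tau_ns")],
    protocol = "one-step", n_pairs = nrow(pair_rates))
  attr(out, "pair_rates") <- pair_rates
  attr(out, "k_total") <- mean(pair_rates$k_pair)
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for FRET rate breakdowns
#'
#' `tidy()` returns the per-state table; `glance()` a one-row summary with
#' the total rate and lifetime.
#'
#' @param x a `fret_breakdown`
#' @param ... ignored
#' @return a tibble
#' @exportS3Method generics::tidy
tidy.fret_breakdown <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "fret_breakdown")
  out
}

#' @rdname tidy.fret_breakdown
#' @exportS3Method generics::glance
glance.fret_breakdown <- function(x, ...) {
  k <- attr(x, "k_total")
  tibble::tibble(
    protocol = attr(x, "protocol"),
    n_states = nrow(x),
    n_pairs = attr(x, "n_pairs"),
    k_total = k,
    tau_total_ns = 1e9 * rate_to_lifetime(k)
  )
}

#' @export
print.fret_breakdown <- function(x, ...) {
  cat(sprintf("FRET rate breakdown (%s protocol)\n", attr(x, "protocol")))
  print(tidy(x), ...)
  cat(sprintf("total k_FRET = %.3g s^-1  (tau = %.3g ns)\n",
              attr(x, "k_total"), 1e9 / attr(x, "k_total")))
  invisible(x)
}

#' Plot a per-state rate breakdown
#'
#' Bar panels of |V_DA|², J and k_FRET per acceptor state, the state-resolved
#' view of which transitions carry the transfer.
#'
#' @param object a `fret_breakdown`
#' @param ... ignored
#' @return a ggplot
#' @exportS3Method ggplot2::autoplot
autoplot.fret_breakdown <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tidy(object)[, c("state", "V2", "overlap_cm", "k_fret")],
    -"state", names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$state, .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "acceptor state", y = NULL)
}
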