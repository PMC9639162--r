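#' Reference vectors as linear combinations of atomic positions
#'
#' A transition dipole computed by quantum chemistry has no counterpart in a
#' classical trajectory. To track its orientation classically, it is mapped
#' onto a proxy vector built from atomic positions, v = sum_k c_k r_k, e.g.
#' the difference of the two imide nitrogens of a perylene diimide, or
#' sum/difference combinations of the six bipyridine nitrogens of a
#' ruthenium tris-bipyridine complex giving one vector along and one
#' perpendicular to the C2 axis. The exact coefficients are user-configurable;
#' the shipped defaults in [ref_spec_nn()] and [ref_spec_bipy()] are a
#' reconstruction of that scheme, not a literal import.
#'
#' @param atoms integer atom indices (1-based)
#' @param coefs signed coefficients, same length
#' @param label name of the vector (e.g. `"v_nn"`, `"v_par"`, `"v_perp"`)
#' @return a `ref_spec` object
#' @export
#' @examples
#' ref_spec(c(1, 2), c(1, -1), "v_nn")
ref_spec <- function(atoms, coefs, label = "v") {
  stopifnot(length(atoms) == length(coefs))
  if (sum(coefs != 0) < 2) {
    stop("a reference vector needs at least two nonzero coefficients", call. = FALSE)
  }
  structure(list(atoms = as.integer(atoms), coefs = as.numeric(coefs),
                 label = label), class = "ref_spec")
}

#' @rdname ref_spec
#' @param n1,n2 indices of the two nitrogens defining the donor N1-N2 vector
#' @export
ref_spec_nn <- function(n1 = 1L, n2 = 2L) ref_spec(c(n1, n2), c(1, -1), "v_nn")

#' @rdname ref_spec
#' @param n_atoms indices of the six bipyridine nitrogens, ordered so that the
#'   first two belong to the bipyridine on the C2 axis
#' @return `ref_spec_bipy`: a list with elements `par` and `perp`.
#' @export
ref_spec_bipy <- function(n_atoms = 1:6) {
  stopifnot(length(n_atoms) == 6)
  list(
    par = ref_spec(n_atoms, c(2, 2, -1, -1, -1, -1) / 4, "v_par"),
    perp = ref_spec(n_atoms[3:6], c(1, 1, -1, -1) / 2, "v_perp")
  )
}

#' Evaluate a reference vector on a geometry
#'
#' @param geometry data frame with columns `x`, `y`, `z` in Å, one row per atom
#' @param spec a [ref_spec()]
#' @return length-3 numeric vector (not normalized)
#' @export
reference_vector <- function(geometry, spec) {
  if (any(spec$atoms < 1 | spec$atoms > nrow(geometry))) {
    stop("reference-vector atom index out of range", call. = FALSE)
  }
  r <- as.matrix(geometry[spec$atoms, c("x", "y", "z")])
  as.numeric(crossprod(r, spec$coefs))
}

#' Squared cosine of the angle between a transition dipole and a reference
#'
#' cos²θ = (u·v)² / (|u|²|v|²). Squaring makes the measure blind to the sign
#' of either vector, which is arbitrary for a transition dipole.
#'
#' @param tdm,ref length-3 numeric vectors, both nonzero
#' @return cos²θ in \[0, 1\]
#' @export
cos2_alignment <- function(tdm, ref) {
  nt <- sum(tdm^2); nr <- sum(ref^2)
  if (nt == 0 || nr == 0) stop("zero vector has no direction", call. = FALSE)
  min(1, sum(tdm * ref)^2 / (nt * nr))
}

#' Alignment diagnostics for an ensemble of transition dipoles
#'
#' Given per-conformer cos²θ against a parallel and a perpendicular reference
#' vector, for each state this reports (i) how many conformers are dominated
#' by each vector (dominant = larger cos²θ; exact ties count as parallel),
#' (ii) the cos² values sorted ascending — a step/sigmoid curve indicates
#' alignment, a near-linear curve indicates orientational disorder — and
#' (iii) a linearity score in \[0, 1\]: one minus the normalized RMS deviation
#' of the sorted curve from the straight ramp between 0 and 1.
#'
#' @param data data frame with columns `state`, `cos2_par`, `cos2_perp`
#' @return list with tibbles `counts` (state, n_par, n_perp, linearity_par,
#'   linearity_perp) and `sorted` (state, rank, quantile, cos2_par, cos2_perp)
#' @export
alignment_profile <- function(data) {
  if (nrow(data) == 0) stop("empty alignment table", call. = FALSE)
  per_state <- function(d) {
    n <- nrow(d)
    dom_par <- d$cos2_par >= d$cos2_perp
    tibble::tibble(
      n_par = sum(dom_par), n_perp = sum(!dom_par),
      linearity_par = linearity_score(sort(d$cos2_par)),
      linearity_perp = linearity_score(sort(d$cos2_perp))
    )
  }
  grouped <- dplyr::group_by(tibble::as_tibble(data), .data$state)
  counts <- dplyr::summarise(grouped, per_state(dplyr::pick(dplyr::everything())),
                             .groups = "drop")
  sorted <- dplyr::reframe(grouped,
    rank = seq_len(dplyr::n()),
    quantile = (seq_len(dplyr::n()) - 0.5) / dplyr::n(),
    cos2_par = sort(.data$cos2_par),
    cos2_perp = sort(.data$cos2_perp))
  list(counts = counts, sorted = sorted)
}

# 1 - RMS deviation of a sorted curve from the linear ramp through its
# quantiles, scaled by the RMS of a step curve vs the ramp (the worst case),
# so 1 = perfectly linear (disordered), 0 = perfect step (fully aligned).
linearity_score <- function(sorted_vals) {
  n <- length(sorted_vals)
  q <- (seq_len(n) - 0.5) / n
  rms <- sqrt(mean((sorted_vals - q)^2))
  rms_step <- sqrt(mean((as.numeric(q > 0.5) - q)^2))  # reference worst case
  max(0, 1 - rms / rms_step)
}

#' Orthogonality defect of a parallel/perpendicular cos² pair
#'
#' If the two reference vectors were exactly perpendicular and the transition
#' dipole lay in their plane, cos²θ_par + cos²θ_perp = 1 exactly. The defect
#' |cos²θ_par + cos²θ_perp - 1| measures how far a conformer deviates from
#' that ideal, through out-of-plane dipole components or distorted reference
#' vectors.
#'
#' @param cos2_par,cos2_perp numeric vectors in \[0, 1\]
#' @param threshold flag defects above this value (default 0.1)
#' @return tibble with columns `defect` and `flagged`
#' @export
orthogonality_defect <- function(cos2_par, cos2_perp, threshold = 0.1) {
  stopifnot(all(cos2_par >= 0 & cos2_par <= 1),
            all(cos2_perp >= 0 & cos2_perp <= 1))
  d <- abs(cos2_par + cos2_perp - 1)
  tibble::tibble(defect = d, flagged = d > threshold)
}

#' Plot sorted alignment curves
#'
#' @param profile result of [alignment_profile()]
#' @return a ggplot faceted by state, with the linear-ramp reference
#' @export
plot_alignment_profile <- function(profile) {
  long <- tidyr::pivot_longer(profile$sorted, c("cos2_par", "cos2_perp"),
                              names_to = "reference", values_to = "cos2")
  ggplot2::ggplot(long, ggplot2::aes(.data$quantile, .data$cos2,
                                     colour = .data$reference)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~state) +
    ggplot2::labs(x = "conformer quantile", y = expression(cos^2 ~ theta))
}
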