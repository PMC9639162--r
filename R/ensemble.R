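#' Boltzmann weights for a conformer ensemble
#'
#' Populations w_i = exp(-E_i / kB T) / sum_j exp(-E_j / kB T), evaluated with
#' the max-shift trick so large relative energies do not underflow. Energies
#' are relative to the ensemble minimum; a uniform shift of all energies
#' leaves the weights unchanged.
#'
#' @param energies relative conformer energies in J
#' @param temperature temperature in K (default 298.15)
#' @return numeric weights summing to 1
#' @export
#' @examples
#' kB <- fret_constants()$kB
#' boltzmann_weights(c(0, kB * 298.15 * log(2)))  # 2:1 population ratio
boltzmann_weights <- function(energies, temperature = 298.15) {
  if (length(energies) == 0) stop("empty energy list", call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  x <- -energies / (.k$kB * temperature)
  x <- x - max(x)
  w <- exp(x)
  w / sum(w)
}

#' Ensemble expectation value
#'
#' Weighted mean <p> = sum_i w_i p_i of a per-conformer property under
#' normalized ensemble weights.
#'
#' @param values per-conformer property values
#' @param weights normalized weights (same length, sum 1)
#' @return scalar expectation value
#' @export
ensemble_expectation <- function(values, weights) {
  if (length(values) != length(weights)) {
    stop("values and weights differ in length", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-8) {
    stop("weights are not normalized", call. = FALSE)
  }
  sum(values * weights)
}

#' Attach Boltzmann weights to a conformer table
#'
#' Takes a data frame with one row per conformer and a relative-energy column,
#' converts the energies to J, and appends a `weight` column. The input order
#' is preserved.
#'
#' @param data data frame with at least the energy column
#' @param energy_col name of the relative-energy column (default `"rel_energy"`)
#' @param energy_unit unit of that column, see [energy_to_joule()]
#' @param temperature temperature in K
#' @return the input as a tibble with an added `weight` column
#' @export
#' @examples
#' conf <- tibble::tibble(id = c("a", "b", "c"), rel_energy = c(0, 2, 8))
#' weight_conformers(conf, energy_unit = "kJ/mol")
weight_conformers <- function(data, energy_col = "rel_energy",
                              energy_unit = "kJ/mol", temperature = 298.15) {
  e <- energy_to_joule(data[[energy_col]], energy_unit)
  if (!any(e == min(e))) stop("no minimum-energy conformer found", call. = FALSE)
  dplyr::mutate(tibble::as_tibble(data),
                weight = boltzmann_weights(e - min(e), temperature))
}

#' Read a delimited conformer table
#'
#' Expects columns `id` and `rel_energy`; the energy unit is declared either
#' via the `energy_unit` argument or a `# energy_unit: <unit>` comment line at
#' the top of the file.
#'
#' @param path file path
#' @param energy_unit energy unit override; if `NULL`, taken from the header
#'   comment, falling back to kJ/mol
#' @return tibble with an `energy_unit` attribute
#' @export
read_conformer_table <- function(path, energy_unit = NULL) {
  head_lines <- readLines(path, n = 5L)
  m <- grep("^#\\s*energy_unit:", head_lines, value = TRUE)
  if (is.null(energy_unit)) {
    energy_unit <- if (length(m)) trimws(sub("^#\\s*energy_unit:", "", m[1])) else "kJ/mol"
  }
  out <- readr::read_delim(path, delim = "\t", comment = "#",
                           show_col_types = FALSE, trim_ws = TRUE)
  attr(out, "energy_unit") <- energy_unit
  out
}
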