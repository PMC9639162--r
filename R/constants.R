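#' Physical constants used throughout the package
#'
#' CODATA 2018 values, SI units. All internal computation is carried out in
#' SI (energies in J, dipoles in C·m, distances in m); Debye, atomic units,
#' eV, cm⁻¹ and Å appear only at the interfaces.
#'
#' @return A named list with elements
#'   \describe{
#'     \item{eps0}{vacuum permittivity, F·m⁻¹}
#'     \item{hbar}{reduced Planck constant, J·s}
#'     \item{h}{Planck constant, J·s}
#'     \item{c}{speed of light, m·s⁻¹}
#'     \item{c_cm}{speed of light, cm·s⁻¹}
#'     \item{kB}{Boltzmann constant, J·K⁻¹}
#'     \item{debye}{1 Debye in C·m}
#'     \item{debye_per_au}{Debye per atomic unit of dipole moment}
#'     \item{hc_Jcm}{h·c with c in cm·s⁻¹; converts cm⁻¹ to J}
#'     \item{eV}{1 eV in J}
#'     \item{hartree}{1 Hartree in J}
#'     \item{avogadro}{Avogadro constant, mol⁻¹}
#'   }
#' @export
#' @examples
#' fret_constants()$hc_Jcm
fret_constants <- function() {
  h <- 6.62607015e-34
  c <- 2.99792458e8
  list(
    eps0 = 8.8541878128e-12,
    hbar = h / (2 * pi),
    h = h,
    c = c,
    c_cm = c * 100,
    kB = 1.380649e-23,
    debye = 1e-21 / c,               # 3.33564e-30 C·m
    debye_per_au = 8.4783536255e-30 / (1e-21 / c), # 2.541746...
    hc_Jcm = h * c * 100,
    eV = 1.602176634e-19,
    hartree = 4.3597447222071e-18,
    avogadro = 6.02214076e23
  )
}

.k <- fret_constants()

#' Unit conversions for dipole strengths, energies, couplings and rates
#'
#' The conversions this pipeline needs, nothing more. `dipole_strength_au2_to_SI()`
#' turns a squared transition dipole (dipole strength) in atomic units into
#' C²·m²; `coupling_to_wavenumber()` expresses a coupling energy in cm⁻¹;
#' `rate_to_lifetime()` inverts a rate into a lifetime.
#'
#' @param mu2 dipole strength in au² (square of the dipole in atomic units)
#' @return `dipole_strength_au2_to_SI`: dipole strength in C²·m².
#' @export
#' @examples
#' dipole_strength_au2_to_SI(23.8)          # donor S1 emission strength
#' sqrt(23.8) * fret_constants()$debye_per_au  # the same strength in Debye
dipole_strength_au2_to_SI <- function(mu2) {
  if (any(mu2 < 0)) stop("dipole strength must be non-negative", call. = FALSE)
  mu2 * (.k$debye_per_au * .k$debye)^2
}

#' @rdname dipole_strength_au2_to_SI
#' @param mu_debye dipole magnitude in Debye
#' @return `debye_to_Cm`: dipole in C·m.
#' @export
debye_to_Cm <- function(mu_debye) mu_debye * .k$debye

#' @rdname dipole_strength_au2_to_SI
#' @param V coupling energy in J (non-negative)
#' @return `coupling_to_wavenumber`: the coupling in cm⁻¹.
#' @export
coupling_to_wavenumber <- function(V) {
  if (any(V < 0)) stop("coupling magnitude must be non-negative", call. = FALSE)
  V / .k$hc_Jcm
}

#' @rdname dipole_strength_au2_to_SI
#' @param k rate in s⁻¹, strictly positive
#' @return `rate_to_lifetime`: lifetime in s.
#' @export
rate_to_lifetime <- function(k) {
  if (any(k <= 0)) stop("rate must be positive to define a lifetime", call. = FALSE)
  1 / k
}

#' @rdname dipole_strength_au2_to_SI
#' @param e_ev energy in eV
#' @return `ev_to_wavenumber`: energy in cm⁻¹.
#' @export
ev_to_wavenumber <- function(e_ev) e_ev * .k$eV / .k$hc_Jcm

#' @rdname dipole_strength_au2_to_SI
#' @param nu energy in cm⁻¹
#' @return `wavenumber_to_ev`: energy in eV.
#' @export
wavenumber_to_ev <- function(nu) nu * .k$hc_Jcm / .k$eV

#' Convert energies between the units conformer tables come in
#'
#' @param x numeric energies
#' @param unit one of `"J"`, `"kJ/mol"`, `"hartree"`, `"eV"`, `"cm-1"`
#' @return energies in J
#' @export
energy_to_joule <- function(x, unit = c("kJ/mol", "J", "hartree", "eV", "cm-1")) {
  unit <- match.arg(unit)
  switch(unit,
    "J" = x,
    "kJ/mol" = x * 1e3 / .k$avogadro,
    "hartree" = x * .k$hartree,
    "eV" = x * .k$eV,
    "cm-1" = x * .k$hc_Jcm
  )
}
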