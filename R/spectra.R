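#' Gaussian convolution of a stick spectrum
#'
#' Builds a continuous line shape on a uniform wavenumber grid as a sum of
#' unit-area Gaussians centered at each vertical transition, weighted by the
#' stick intensity and an optional per-stick (e.g. Boltzmann) weight. The full
#' width at half maximum is given in eV, the standard line-width convention of
#' quantum-chemistry spectra, and converted to cm⁻¹ before evaluation
#' (sigma = fwhm / (2 sqrt(2 ln 2))).
#'
#' A spectral shift (such as the blue-shift used to match a computed band to
#' its experimental maximum) is never inferred: it must be supplied through
#' `shift_ev` and is recorded in the result's `shift_ev` attribute.
#'
#' @param sticks data frame with columns `energy_ev` and `intensity`,
#'   optionally `weight`
#' @param fwhm_ev full width at half maximum of the Gaussian line shape, eV
#' @param shift_ev rigid shift applied to all stick energies before
#'   convolution, eV (default 0)
#' @param grid_step grid spacing in cm⁻¹ (default 1)
#' @param grid_range optional c(min, max) wavenumber range in cm⁻¹; default
#'   spans all (shifted) sticks ± 5 fwhm
#' @param normalize normalize the result to unit trapezoidal area
#' @return a `fret_spectrum`: tibble with columns `wavenumber` (cm⁻¹) and
#'   `density` (per cm⁻¹), attributes `normalized` and `shift_ev`
#' @export
#' @examples
#' s <- tibble::tibble(energy_ev = 2.0, intensity = 1)
#' sp <- convolve_sticks(s, fwhm_ev = 0.05)
#' spectrum_area(sp)
convolve_sticks <- function(sticks, fwhm_ev, shift_ev = 0, grid_step = 1,
                            grid_range = NULL, normalize = TRUE) {
  stopifnot(fwhm_ev > 0, grid_step > 0)
  if (any(sticks$intensity < 0)) stop("stick intensities must be >= 0", call. = FALSE)
  e_cm <- ev_to_wavenumber(sticks$energy_ev + shift_ev)
  fwhm_cm <- ev_to_wavenumber(fwhm_ev)
  sigma <- fwhm_cm / (2 * sqrt(2 * log(2)))
  w <- if ("weight" %in% names(sticks)) sticks$weight else rep(1, nrow(sticks))
  if (is.null(grid_range)) {
    grid_range <- c(min(e_cm) - 5 * fwhm_cm, max(e_cm) + 5 * fwhm_cm)
  } else {
    truncated <- e_cm < grid_range[1] + 5 * fwhm_cm | e_cm > grid_range[2] - 5 * fwhm_cm
    if (any(truncated)) {
      stop(sprintf(
        "grid [%g, %g] cm-1 truncates stick(s) at %s cm-1 (need +/- 5 fwhm)",
        grid_range[1], grid_range[2],
        paste(signif(e_cm[truncated], 6), collapse = ", ")
      ), call. = FALSE)
    }
  }
  grid <- seq(grid_range[1], grid_range[2], by = grid_step)
  dens <- rep(0, length(grid))
  amp <- sticks$intensity * w
  for (i in seq_along(e_cm)) {
    dens <- dens + amp[i] * stats::dnorm(grid, mean = e_cm[i], sd = sigma)
  }
  sp <- new_fret_spectrum(grid, dens, normalized = FALSE, shift_ev = shift_ev)
  if (normalize) normalize_spectrum(sp) else sp
}

new_fret_spectrum <- function(wavenumber, density, normalized = FALSE,
                              shift_ev = 0) {
  out <- tibble::tibble(wavenumber = wavenumber, density = density)
  class(out) <- c("fret_spectrum", class(out))
  attr(out, "normalized") <- normalized
  attr(out, "shift_ev") <- shift_ev
  out
}

#' @rdname convolve_sticks
#' @param spectrum a `fret_spectrum`
#' @return `spectrum_area`: the trapezoidal integral over the grid.
#' @export
spectrum_area <- function(spectrum) {
  pracma::trapz(spectrum$wavenumber, spectrum$density)
}

#' @rdname convolve_sticks
#' @export
normalize_spectrum <- function(spectrum) {
  a <- spectrum_area(spectrum)
  if (a <= 0) stop("cannot normalize a spectrum with non-positive area", call. = FALSE)
  out <- new_fret_spectrum(spectrum$wavenumber, spectrum$density / a,
                           normalized = TRUE,
                           shift_ev = attr(spectrum, "shift_ev") %||% 0)
  out
}

#' Spectral overlap of two unit-area line shapes
#'
#' J = integral of f_D(nu) f_A(nu) d nu on the wavenumber axis, evaluated by
#' the trapezoid rule after resampling both spectra onto the union grid at the
#' finer of the two spacings. Because both densities are per cm⁻¹ and the
#' integration variable is cm⁻¹, J carries the unit cm.
#'
#' @param donor_emission normalized `fret_spectrum` (donor fluorescence)
#' @param acceptor_absorption normalized `fret_spectrum` (acceptor absorption)
#' @return overlap J in cm
#' @export
overlap_numeric <- function(donor_emission, acceptor_absorption) {
  for (sp in list(donor_emission, acceptor_absorption)) {
    if (!isTRUE(attr(sp, "normalized"))) {
      stop("spectra must be normalized to unit area before computing overlap",
           call. = FALSE)
    }
  }
  lo <- max(min(donor_emission$wavenumber), min(acceptor_absorption$wavenumber))
  hi <- min(max(donor_emission$wavenumber), max(acceptor_absorption$wavenumber))
  if (lo >= hi) return(0)
  step <- min(diff(donor_emission$wavenumber[1:2]),
              diff(acceptor_absorption$wavenumber[1:2]))
  grid <- seq(lo, hi, by = step)
  fd <- stats::approx(donor_emission$wavenumber, donor_emission$density,
                      xout = grid, rule = 2)$y
  fa <- stats::approx(acceptor_absorption$wavenumber, acceptor_absorption$density,
                      xout = grid, rule = 2)$y
  pracma::trapz(grid, fd * fa)
}

#' Closed-form overlap of two Gaussian line shapes
#'
#' For two unit-area Gaussians on the wavenumber axis, centered at the donor
#' and acceptor vertical excitation energies with widths sigma_D and sigma_A
#' (from the respective fwhm values), the overlap integral has the closed form
#'
#'   J = exp(-d^2 / (2 (sigma_D^2 + sigma_A^2))) / sqrt(2 pi (sigma_D^2 + sigma_A^2))
#'
#' with d the center separation, everything in cm⁻¹, so J comes out in cm.
#' This is the per-pair overlap used by the one-step protocol, where each
#' snapshot's transition is represented by a single Gaussian.
#'
#' All arguments are vectorized.
#'
#' @param e_d,e_a donor and acceptor vertical excitation energies, eV
#' @param fwhm_d,fwhm_a Gaussian full widths at half maximum, eV
#' @return overlap J in cm
#' @export
#' @examples
#' overlap_gaussian_pair(2.2, 0.05, 2.2, 0.2)
overlap_gaussian_pair <- function(e_d, fwhm_d, e_a, fwhm_a) {
  stopifnot(all(fwhm_d > 0), all(fwhm_a > 0))
  s2 <- (ev_to_wavenumber(fwhm_d)^2 + ev_to_wavenumber(fwhm_a)^2) /
    (2 * sqrt(2 * log(2)))^2
  delta <- ev_to_wavenumber(e_d - e_a)
  exp(-delta^2 / (2 * s2)) / sqrt(2 * pi * s2)
}

#' Read / write two-column spectra and stick lists
#'
#' Plain delimited text: spectra as (wavenumber, density), stick lists as
#' (energy_ev, intensity) with optional weight and conformer id columns.
#'
#' @param path file path
#' @return `read_sticks`: tibble of sticks; `read_spectrum_table`: a
#'   `fret_spectrum` (unnormalized).
#' @export
read_sticks <- function(path) {
  readr::read_delim(path, delim = "\t", comment = "#",
                    show_col_types = FALSE, trim_ws = TRUE)
}

#' @rdname read_sticks
#' @export
read_spectrum_table <- function(path) {
  d <- readr::read_delim(path, delim = "\t", comment = "#",
                         show_col_types = FALSE, trim_ws = TRUE)
  new_fret_spectrum(d[[1]], d[[2]], normalized = FALSE)
}

#' @rdname read_sticks
#' @param spectrum a `fret_spectrum`
#' @export
write_spectrum_table <- function(spectrum, path) {
  readr::write_tsv(tibble::tibble(wavenumber = spectrum$wavenumber,
                                  density = spectrum$density), path)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spectrum
#'
#' @param object a `fret_spectrum`
#' @param ... ignored
#' @return a ggplot
#' @exportS3Method ggplot2::autoplot
autoplot.fret_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$wavenumber, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(tilde(nu) ~ (cm^-1)),
                  y = expression(density ~ (cm)))
}
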