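#' Orientation factor kappa
#'
#' kappa = mu_D_hat · mu_A_hat - 3 (mu_D_hat · r_hat)(mu_A_hat · r_hat) for
#' unit vectors along the two transition dipoles and the separation. kappa
#' lies in \[-2, 2\], so kappa² spans \[0, 4\] with isotropic average 2/3.
#'
#' @param mu_d_hat,mu_a_hat,r_hat unit 3-vectors (|v| within 1e-8 of 1)
#' @return kappa (signed)
#' @export
#' @examples
#' kappa_factor(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1))  # collinear: kappa = -2
kappa_factor <- function(mu_d_hat, mu_a_hat, r_hat) {
  for (v in list(mu_d_hat, mu_a_hat, r_hat)) {
    if (abs(sqrt(sum(v^2)) - 1) > 1e-8) {
      stop("kappa expects unit vectors", call. = FALSE)
    }
  }
  sum(mu_d_hat * mu_a_hat) -
    3 * sum(mu_d_hat * r_hat) * sum(mu_a_hat * r_hat)
}

#' Membrane-frame transition dipole vector
#'
#' The membrane confines a chromophore's tilt (angle phi to the xy membrane
#' plane) but leaves rotation about the membrane normal free. A representative
#' dipole of magnitude mu at tilt phi and azimuth varphi is
#' mu · (cos phi cos varphi, cos phi sin varphi, sin phi).
#'
#' @param strength_debye dipole magnitude in Debye
#' @param tilt_deg angle to the xy-plane, degrees, in \[-90, 90\]
#' @param azimuth_deg rotation about z, degrees (default 0: vector in the
#'   xz-plane)
#' @return length-3 dipole vector in C·m
#' @export
membrane_tdm <- function(strength_debye, tilt_deg, azimuth_deg = 0) {
  stopifnot(strength_debye >= 0, abs(tilt_deg) <= 90)
  phi <- tilt_deg * pi / 180
  az <- azimuth_deg * pi / 180
  debye_to_Cm(strength_debye) *
    c(cos(phi) * cos(az), cos(phi) * sin(az), sin(phi))
}

#' Squared point-dipole coupling between two transition dipoles
#'
#' The screened point-dipole interaction
#' V = (mu_D · mu_A - 3 (mu_D · r_hat)(mu_A · r_hat)) / (4 pi eps0 eta² r³),
#' i.e. V = kappa |mu_D||mu_A| / (4 pi eps0 eta² r³). The medium's refractive
#' index eta screens the field as eta². Returns V² in J² (kg² m⁴ s⁻⁴), the
#' unit the per-state coupling tables are reported in.
#'
#' @param mu_d,mu_a dipole vectors in C·m
#' @param r_angstrom separation magnitude in Å, > 0
#' @param eta medium refractive index, >= 1
#' @param r_hat unit separation vector (default along z, the membrane normal)
#' @return |V_DA|² in J²
#' @export
coupling_squared <- function(mu_d, mu_a, r_angstrom, eta = 1.478,
                             r_hat = c(0, 0, 1)) {
  if (r_angstrom <= 0) stop("separation must be positive", call. = FALSE)
  stopifnot(eta >= 1)
  r_m <- r_angstrom * 1e-10
  V <- (sum(mu_d * mu_a) - 3 * sum(mu_d * r_hat) * sum(mu_a * r_hat)) /
    (4 * pi * .k$eps0 * eta^2 * r_m^3)
  V^2
}

#' Azimuthally averaged squared coupling
#'
#' The donor dipole is kept fixed in the xz-plane and the acceptor dipole is
#' rotated about the membrane normal over a uniform azimuth grid (default
#' 0–359° in 1° steps); |V_DA|² is evaluated at every grid point and
#' arithmetically averaged. With the separation along z, the grid average has
#' the closed form
#' <kappa²> = 1/2 cos²phi_D cos²phi_A + 4 sin²phi_D sin²phi_A
#' times the orientation-independent prefactor — see
#' [kappa2_mean_closed()], which the grid result matches to machine precision.
#'
#' @param donor_debye,donor_tilt_deg donor dipole magnitude (D) and tilt (deg)
#' @param acceptor_debye,acceptor_tilt_deg acceptor magnitude (D) and tilt (deg)
#' @param r_angstrom separation along the membrane normal, Å
#' @param eta medium refractive index
#' @param azimuth_step_deg azimuth grid step in degrees (default 1)
#' @return <|V_DA|²> in J²
#' @export
#' @examples
#' rotational_average_V2(12.3, 11.7, 3.2, 29.6, r_angstrom = 33.4)
rotational_average_V2 <- function(donor_debye, donor_tilt_deg,
                                  acceptor_debye, acceptor_tilt_deg,
                                  r_angstrom, eta = 1.478,
                                  azimuth_step_deg = 1) {
  mu_d <- membrane_tdm(donor_debye, donor_tilt_deg, azimuth_deg = 0)
  az <- seq(0, 360 - azimuth_step_deg, by = azimuth_step_deg)
  v2 <- vapply(az, function(a) {
    coupling_squared(mu_d, membrane_tdm(acceptor_debye, acceptor_tilt_deg, a),
                     r_angstrom, eta)
  }, numeric(1))
  mean(v2)
}

#' @rdname rotational_average_V2
#' @param tilt_d_deg,tilt_a_deg tilts of the two dipoles to the membrane
#'   plane, degrees
#' @return `kappa2_mean_closed`: the analytic azimuthal mean of kappa².
#' @export
kappa2_mean_closed <- function(tilt_d_deg, tilt_a_deg) {
  pd <- tilt_d_deg * pi / 180
  pa <- tilt_a_deg * pi / 180
  0.5 * cos(pd)^2 * cos(pa)^2 + 4 * sin(pd)^2 * sin(pa)^2
}

# Azimuthal grid mean of kappa² for arbitrary unit vectors, separation along
# z, vectorized over rows of the acceptor matrix. kappa(phi) expands as
# X cos(phi) + Y sin(phi) + W with W = -2 c s; the grid mean of kappa² is
# assembled from the trigonometric moments of the actual azimuth grid, which
# is algebraically identical to evaluating kappa at every grid point.
azimuthal_kappa2_mean <- function(u_d, u_a, azimuth_step_deg = 1) {
  if (is.null(dim(u_a))) u_a <- matrix(u_a, nrow = 1)
  if (is.null(dim(u_d))) u_d <- matrix(u_d, nrow = 1)
  phi <- seq(0, 360 - azimuth_step_deg, by = azimuth_step_deg) * pi / 180
  m_c <- mean(cos(phi)); m_s <- mean(sin(phi))
  m_cc <- mean(cos(phi)^2); m_ss <- mean(sin(phi)^2)
  m_cs <- mean(cos(phi) * sin(phi))
  a <- u_d[, 1]; b <- u_d[, 2]; cc <- u_d[, 3]
  p <- u_a[, 1]; q <- u_a[, 2]; s <- u_a[, 3]
  X <- a * p + b * q
  Y <- b * p - a * q
  W <- -2 * cc * s
  X^2 * m_cc + Y^2 * m_ss + W^2 + 2 * X * Y * m_cs + 2 * X * W * m_c +
    2 * Y * W * m_s
}

#' Monte-Carlo isotropic average of kappa²
#'
#' Draws both dipole orientations uniformly on the sphere and averages
#' kappa²; converges to the textbook isotropic value 2/3.
#'
#' @param n number of samples
#' @return list with `mean`, `se` (standard error) and `n`
#' @export
kappa2_isotropic_mc <- function(n = 1e6) {
  ud <- random_unit_vectors(n)
  ua <- random_unit_vectors(n)
  k <- rowSums(ud * ua) - 3 * ud[, 3] * ua[, 3]  # r_hat = z WLOG
  k2 <- k^2
  list(mean = mean(k2), se = stats::sd(k2) / sqrt(n), n = n)
}

random_unit_vectors <- function(n) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

#' Brute-force maximum of kappa² on an orientation grid
#'
#' Scans donor and acceptor polar/azimuth orientations on a regular grid and
#' returns the largest kappa² encountered; attains 4 (both dipoles along the
#' separation axis) for any grid containing the poles.
#'
#' @param step_deg grid step in degrees
#' @return maximum kappa² found
#' @export
kappa2_max_grid <- function(step_deg = 1) {
  th <- seq(0, 180, by = step_deg) * pi / 180
  # by symmetry kappa depends on the two polar angles and the azimuth
  # difference only, so a 3-angle scan covers all orientation pairs
  dphi <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  best <- 0
  cd <- cos(th); sd_ <- sin(th)
  for (i in seq_along(th)) {
    for (j in seq_along(th)) {
      dot <- sd_[i] * sd_[j] * cos(dphi) + cd[i] * cd[j]
      kk <- (dot - 3 * cd[i] * cd[j])^2
      m <- max(kk)
      if (m > best) best <- m
    }
  }
  best
}
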