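#' @title Rate theories and unit conversions
#' @description Eyring transition-state theory, the thermally averaged
#'   double-passage Landau-Zener intersystem-crossing prefactor and rate,
#'   effective activation free energies and entropies, half-lives, and
#'   energy-to-wavelength conversions. All constants come from the central
#'   [azo_constants] table.
#' @name kinetics
NULL

#' Eyring rate constant
#'
#' k = (k_B T / h) exp(-dG_dagger / RT), transmission coefficient 1.
#'
#' @param dG_dagger activation free energy, kcal/mol.
#' @param T temperature, K.
#' @return first-order rate constant, 1/s.
#' @export
eyring_rate <- function(dG_dagger, T = 298.15) {
  if (any(T <= 0)) stop("temperature must be positive")
  k <- azo_constants
  RT <- k$R_gas * T / k$J_per_kcal
  (k$kB * T / k$h) * exp(-dG_dagger / RT)
}

#' Thermally averaged Landau-Zener ISC rate prefactor
#'
#' The Eyring prefactor k_B T / h is replaced by
#' k_ISC = (k_B T / h) <P>, with <P> the Boltzmann average over
#' seam-normal kinetic energy E of the double-passage surface-hopping
#' probability P(E) = p + (1 - p) p, where the single-passage
#' Landau-Zener probability is
#' p(E) = 1 - exp(-2 pi H_SO^2 / (hbar dF) sqrt(mu / (2 E))).
#' The thermal average <P> = (1/k_B T) integral_0^inf P(E) e^(-E/k_B T) dE
#' is evaluated by adaptive quadrature. In the weak-coupling limit the
#' prefactor scales as H_SO^2.
#'
#' @param H_SO spin-orbit coupling constant, cm^-1 (default 20).
#' @param dF norm of the S0/T1 gradient difference at the crossing,
#'   kcal/mol per mass-weighted angstrom (i.e. per angstrom sqrt(amu)).
#' @param mu effective mass along the seam normal in amu; 1 by the
#'   mass-weighted-coordinate convention.
#' @param T temperature, K.
#' @return ISC rate prefactor, 1/s.
#' @export
isc_prefactor <- function(H_SO = 20, dF, mu = 1, T = 298.15) {
  if (dF <= 0) stop("degenerate seam: dF must be positive")
  if (mu <= 0 || T <= 0) stop("mu and T must be positive")
  if (H_SO < 0) stop("H_SO must be nonnegative")
  if (H_SO == 0) return(0)
  k <- azo_constants
  Hj <- H_SO * k$cm1_J
  # dF in kcal/mol per (angstrom sqrt(amu)) -> J per (m sqrt(kg))
  dF_si <- dF * k$J_per_kcal / k$NA_avogadro / (1e-10 * sqrt(k$amu_kg))
  kT <- k$kB * T
  # single-passage LZ exponent: a / sqrt(E), E in J
  a <- 2 * pi * Hj^2 / (k$hbar * dF_si) * sqrt(mu / 2)
  P_of_E <- function(E) {
    p <- -expm1(-a / sqrt(E))
    p + (1 - p) * p
  }
  # substitute E = t^2 kT: removes the 1/sqrt(E) endpoint behavior of
  # the Landau-Zener exponent, leaving a smooth bounded integrand
  integrand <- function(t) P_of_E(t^2 * kT) * exp(-t^2) * 2 * t
  avg <- stats::integrate(integrand, 0, 9, rel.tol = 1e-11,
                          subdivisions = 800L)$value
  (kT / k$h) * avg
}

#' ISC-based rate constant
#'
#' k = k_ISC exp(-dG_X / RT): the Eyring form with the prefactor
#' replaced by the ISC prefactor and the activation free energy replaced
#' by the free-energy difference at the singlet-triplet crossing.
#'
#' @param k_isc_prefactor ISC prefactor from [isc_prefactor()], 1/s.
#' @param dG_X free-energy difference reactant -> crossing, kcal/mol.
#' @param T temperature, K.
#' @return rate constant, 1/s.
#' @export
isc_rate <- function(k_isc_prefactor, dG_X, T = 298.15) {
  if (T <= 0) stop("temperature must be positive")
  k <- azo_constants
  RT <- k$R_gas * T / k$J_per_kcal
  k_isc_prefactor * exp(-dG_X / RT)
}

#' Effective activation free energy
#'
#' The exact inverse of [eyring_rate()]: the barrier an Eyring rate
#' expression would need to reproduce a given rate constant,
#' dG_eff = -RT ln(k h / (k_B T)). Applied to an ISC rate this converts
#' the nonadiabatic rate into the familiar activation-free-energy form.
#'
#' @param k rate constant, 1/s (must be positive).
#' @param T temperature, K.
#' @return effective activation free energy, kcal/mol.
#' @export
effective_activation <- function(k, T = 298.15) {
  if (any(k <= 0)) stop("rate must be positive")
  kc <- azo_constants
  RT <- kc$R_gas * T / kc$J_per_kcal
  -RT * log(k * kc$h / (kc$kB * T))
}

#' Effective activation entropy
#'
#' dS_eff = dS_X + R ln(k_ISC / (k_B T / h)), evaluated at fixed
#' temperature (no temperature derivative of the prefactor). When
#' k_ISC < k_B T / h the logarithm is negative, which is what drives the
#' characteristically negative effective activation entropies of
#' triplet-mediated isomerization.
#'
#' @param dS_X activation entropy at the crossing, J/(mol K).
#' @param k_isc_prefactor ISC prefactor, 1/s.
#' @param T temperature, K.
#' @return effective activation entropy, J/(mol K).
#' @export
effective_entropy <- function(dS_X, k_isc_prefactor, T = 298.15) {
  if (T <= 0 || k_isc_prefactor <= 0)
    stop("T and the prefactor must be positive")
  k <- azo_constants
  dS_X + k$R_gas * log(k_isc_prefactor / (k$kB * T / k$h))
}

#' Entropic contribution to a free energy
#'
#' Returns -T dS converted to kcal/mol (1 kcal = 4184 J).
#'
#' @param dS entropy, J/(mol K).
#' @param T temperature, K.
#' @return -T dS in kcal/mol.
#' @export
entropic_term <- function(dS, T = 298.15) {
  if (T <= 0) stop("temperature must be positive")
  -T * dS / azo_constants$J_per_kcal
}

#' First-order half-life
#'
#' t_1/2 = ln 2 / k.
#'
#' @param k rate constant, 1/s (must be positive).
#' @return half-life, s.
#' @export
half_life <- function(k) {
  if (any(k <= 0)) stop("rate must be positive")
  log(2) / k
}

#' Convert a vertical gap to a wavelength
#'
#' lambda = h c N_A / dE with h c N_A = 28591 kcal nm / mol.
#'
#' @param dE vertical excitation energy, kcal/mol (positive).
#' @return wavelength, nm.
#' @export
gap_wavelength <- function(dE) {
  if (any(dE <= 0)) stop("gap must be positive")
  azo_constants$hcNA_kcal_nm / dE
}

#' First-order wavelength error from a gap error
#'
#' delta-lambda = lambda0^2 dE_err / (h c N_A): the first-order
#' propagation of a vertical-gap energy error into a wavelength error at
#' a nominal absorption wavelength.
#'
#' @param dE_err gap error, kcal/mol (nonnegative).
#' @param lambda0 nominal wavelength, nm (positive).
#' @return wavelength error, nm.
#' @export
wavelength_error <- function(dE_err, lambda0) {
  if (any(dE_err < 0) || any(lambda0 <= 0))
    stop("dE_err must be nonnegative and lambda0 positive")
  lambda0^2 * dE_err / azo_constants$hcNA_kcal_nm
}
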