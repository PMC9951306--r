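#' Physical constants used throughout the package
#'
#' A single table of CODATA values and derived conversion factors. All
#' rate, thermochemistry, and unit-conversion code draws from this list so
#' that conversions are consistent and round-trip exactly.
#'
#' Energies are carried in kcal/mol, geometry in angstrom, entropy in
#' J/(mol K), frequencies in cm^-1, masses in amu.
#'
#' @format A named list:
#' \describe{
#'   \item{kB}{Boltzmann constant, J/K}
#'   \item{h}{Planck constant, J s}
#'   \item{hbar}{Reduced Planck constant, J s}
#'   \item{c}{Speed of light, cm/s (for wavenumber conversions)}
#'   \item{NA_avogadro}{Avogadro constant, 1/mol}
#'   \item{R_gas}{Molar gas constant, J/(mol K)}
#'   \item{J_per_kcal}{Joules per thermochemical kilocalorie (4184 exactly)}
#'   \item{amu_kg}{Atomic mass unit, kg}
#'   \item{cm1_J}{Energy of one wavenumber, J}
#'   \item{hcNA_kcal_nm}{h*c*N_A in kcal nm / mol, for gap-to-wavelength}
#' }
#' @export
azo_constants <- local({
  kB <- 1.380649e-23
  h <- 6.62607015e-34
  c_cm <- 2.99792458e10
  NAv <- 6.02214076e23
  list(
    kB = kB,
    h = h,
    hbar = h / (2 * pi),
    c = c_cm,
    NA_avogadro = NAv,
    R_gas = kB * NAv,                 # 8.31446...
    J_per_kcal = 4184,
    amu_kg = 1.66053906660e-27,
    cm1_J = h * c_cm,                 # 1.98645e-23 J per cm^-1
    hcNA_kcal_nm = 28591              # conventional value for wavelength work
  )
})

# kcal/mol -> J per molecule
.kcalmol_to_J <- function(e) e * azo_constants$J_per_kcal / azo_constants$NA_avogadro

# atomic masses (amu), enough for azo photoswitch chemistry
.atomic_masses <- c(
  H = 1.008, He = 4.0026, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
  Br = 79.904, I = 126.90
)

# covalent radii (angstrom), Cordero 2008 consensus values
.covalent_radii <- c(
  H = 0.31, He = 0.28, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
  F = 0.57, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02,
  Br = 1.20, I = 1.39
)

.atomic_numbers <- c(
  H = 1, He = 2, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14,
  P = 15, S = 16, Cl = 17, Br = 35, I = 53
)

#' Look up atomic masses
#' @param elements character vector of element symbols
#' @return numeric vector of masses in amu
#' @export
atomic_mass <- function(elements) {
  m <- .atomic_masses[elements]
  if (anyNA(m)) {
    stop("unknown element(s): ",
         paste(unique(elements[is.na(m)]), collapse = ", "))
  }
  unname(m)
}
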