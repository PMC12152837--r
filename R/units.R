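## Physical constants and unit helpers.
## Internal conventions: q in nm^-1, lengths in nm, electron densities in
## e/A^3, absolute intensities in cm^-1.  Conversions happen at the few
## places where mixed-unit formulas are evaluated, via the helpers below.

#' Physical constants used throughout the package
#'
#' @format A named list with components
#'   \describe{
#'     \item{r0_cm}{classical electron radius, cm (0.28179e-12)}
#'     \item{N_A}{Avogadro constant, mol^-1}
#'     \item{kB_J}{Boltzmann constant, J K^-1}
#'     \item{e_C}{elementary charge, C}
#'     \item{eps0}{vacuum permittivity, F m^-1}
#'   }
#' @export
micelle_constants <- list(
  r0_cm = 0.28179e-12,
  N_A   = 6.02214076e23,
  kB_J  = 1.380649e-23,
  e_C   = 1.602176634e-19,
  eps0  = 8.8541878128e-12
)

#' Convert nanometres to Angstroms and back
#'
#' @param x numeric vector of lengths.
#' @return `nm_to_angstrom(x)` returns `10 * x`; `angstrom_to_nm(x)` returns
#'   `x / 10`.
#' @export
nm_to_angstrom <- function(x) 10 * x

#' @rdname nm_to_angstrom
#' @export
angstrom_to_nm <- function(x) x / 10

#' Electron density conversion e/A^3 -> e/cm^3
#'
#' 1 A^-3 = 1e24 cm^-3 exactly.
#'
#' @param rho electron density in e/A^3.
#' @return electron density in e/cm^3.
#' @export
edens_A3_to_cm3 <- function(rho) rho * 1e24

#' Bjerrum length in water-like solvents
#'
#' lambda_B = e^2 / (4 pi eps0 eps_r kB T), the separation at which the
#' Coulomb energy of two unit charges equals kB T.
#'
#' @param temperature absolute temperature, K.
#' @param dielectric_const relative dielectric constant of the solvent.
#' @return Bjerrum length in nm (about 0.714 nm for water at 298 K).
#' @export
bjerrum_length <- function(temperature = 298, dielectric_const = 78.5) {
  cc <- micelle_constants
  lb_m <- cc$e_C^2 / (4 * pi * cc$eps0 * dielectric_const * cc$kB_J * temperature)
  lb_m * 1e9
}

## internal validators -------------------------------------------------------

check_qgrid <- function(q) {
  if (!is.numeric(q) || length(q) < 1L || any(!is.finite(q))) {
    stop("q grid must be a finite numeric vector", call. = FALSE)
  }
  if (any(q <= 0)) stop("q grid must be strictly positive (nm^-1)", call. = FALSE)
  if (is.unsorted(q, strictly = TRUE)) {
    stop("q grid must be strictly increasing with no duplicates", call. = FALSE)
  }
  invisible(q)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
  }
  invisible(x)
}
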