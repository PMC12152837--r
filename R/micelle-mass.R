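## Model-independent micelle molar mass and association number from
## absolute-scale forward scattering, with Tanford chain-volume and
## electron-density helpers.

#' Tanford volume of a saturated alkyl chain
#'
#' v_l = 27.4 + 26.9 n (Angstrom^3), where n is the number of chain carbons
#' excluding the terminal CH3 group.
#'
#' @param n_carbons number of carbons, >= 0.
#' @return chain volume, Angstrom^3.
#' @export
tanford_volume <- function(n_carbons) {
  if (any(n_carbons < 0)) stop("'n_carbons' must be >= 0", call. = FALSE)
  27.4 + 26.9 * n_carbons
}

#' Electron density of a chain segment
#'
#' @param n_electrons electrons contained in the volume.
#' @param v_l volume, Angstrom^3.
#' @return electron density, e/A^3.
#' @export
tail_electron_density <- function(n_electrons, v_l) {
  if (any(v_l <= 0)) stop("'v_l' must be > 0", call. = FALSE)
  if (any(n_electrons <= 0)) stop("'n_electrons' must be > 0", call. = FALSE)
  n_electrons / v_l
}

#' Contrast inputs for the forward-scattering mass relation
#'
#' Everything the absolute-intensity mass formula needs.  On absolute scale
#' the forward scattering of a dilute particle solution is
#' I(0) = c M \[r0 v_p (rho_l - rho_0)\]^2 / N_A, so the molar mass follows
#' model-independently from I(0), the concentration and the electron-density
#' contrast.
#'
#' @param i0 forward scattering intensity I(0), cm^-1, > 0.
#' @param c_mic particle mass concentration, g cm^-3, > 0.
#' @param v_p partial specific volume, cm^3 g^-1, > 0.
#' @param rho_l particle electron density, e/A^3.
#' @param rho_0 solvent electron density, e/A^3 (water: 0.333).
#' @return an object of class `"contrast_inputs"`.
#' @export
contrast_inputs <- function(i0, c_mic, v_p = 1.17, rho_l = 0.291,
                            rho_0 = 0.333) {
  check_positive_scalar(i0, "i0")
  check_positive_scalar(c_mic, "c_mic")
  check_positive_scalar(v_p, "v_p")
  check_positive_scalar(rho_0, "rho_0")
  structure(list(i0 = i0, c_mic = c_mic, v_p = v_p, rho_l = rho_l,
                 rho_0 = rho_0), class = "contrast_inputs")
}

#' Micelle molar mass from absolute forward scattering
#'
#' M_mic = I(0) N_A / (c_mic \[r0 v_p (rho_l - rho_0)\]^2), with electron
#' densities converted from e/A^3 to e/cm^3 (x 1e24) and
#' r0 = 0.28179e-12 cm.
#'
#' @param inputs a [contrast_inputs()] object.
#' @return a list of class `"mass_result"` with `m_mic` (g/mol) and the
#'   echoed inputs; combine with [association_number()] for p.
#' @export
micelle_molar_mass <- function(inputs) {
  if (!inherits(inputs, "contrast_inputs")) {
    stop("'inputs' must be a contrast_inputs object", call. = FALSE)
  }
  drho <- edens_A3_to_cm3(inputs$rho_l - inputs$rho_0)   # e/cm^3
  if (drho == 0) stop("degenerate contrast: rho_l equals rho_0",
                      call. = FALSE)
  denom <- inputs$c_mic * (micelle_constants$r0_cm * inputs$v_p * drho)^2
  m <- inputs$i0 * micelle_constants$N_A / denom
  structure(list(m_mic = m, inputs = inputs), class = "mass_result")
}

#' @export
print.mass_result <- function(x, ...) {
  cat(sprintf("Micelle molar mass: %.4g g/mol  (I(0) = %g cm^-1, c = %g g/cm^3, contrast = %+.3f e/A^3)\n",
              x$m_mic, x$inputs$i0, x$inputs$c_mic,
              x$inputs$rho_l - x$inputs$rho_0))
  invisible(x)
}

#' Association number
#'
#' p = M_mic / M_mol, the number of molecules per micelle.
#'
#' @param m_mic micelle molar mass, g/mol.
#' @param m_mol monomer molar mass, g/mol (semaglutide: 4113.6).
#' @return dimensionless association number.
#' @export
association_number <- function(m_mic, m_mol = 4113.6) {
  if (any(m_mol <= 0)) stop("'m_mol' must be > 0", call. = FALSE)
  if (any(m_mic <= 0)) stop("'m_mic' must be > 0", call. = FALSE)
  m_mic / m_mol
}

#' Association-number estimate from a low-q intensity ratio
#'
#' The concentration-normalized intensity at a low-q probe point scales with
#' the aggregate mass, so the ratio between a concentrated and a dilute
#' curve, multiplied by the dilute-solution reference association number,
#' gives a rough p estimate for the concentrated sample.  A structure-factor
#' interference peak in the concentrated curve depresses low-q intensity and
#' biases the estimate; the result is flagged when one is detected.
#'
#' @param curve_hi,curve_lo [saxs_curve()]s with concentration metadata.
#' @param q_probe probe wavenumber, nm^-1 (nearest grid point; linear
#'   interpolation when the probe falls between points).
#' @param p_ref association number of the dilute reference.
#' @return a list with `p_estimate`, `intensity_ratio` and
#'   `structure_factor_warning`.
#' @export
ratio_association_estimate <- function(curve_hi, curve_lo, q_probe = 0.1,
                                       p_ref = 2.2) {
  c_hi <- attr(curve_hi, "concentration")
  c_lo <- attr(curve_lo, "concentration")
  if (is.null(c_hi) || is.null(c_lo)) {
    stop("both curves need concentration metadata", call. = FALSE)
  }
  probe <- function(curve) {
    i <- which.min(abs(curve$q - q_probe))
    if (abs(curve$q[i] - q_probe) / q_probe < 0.02) curve$intensity[i]
    else stats::approx(curve$q, curve$intensity, xout = q_probe)$y
  }
  ratio <- (probe(curve_hi) / c_hi) / (probe(curve_lo) / c_lo)
  ## crude peak detection: an interior point standing >3% above the curve
  ## several points to either side marks an interference maximum
  ii <- curve_hi$intensity
  n <- length(ii)
  has_peak <- FALSE
  if (n > 14L) {
    m <- 7:(n - 7L)
    has_peak <- any(ii[m] > 1.03 * ii[m - 6L] & ii[m] > 1.03 * ii[m + 6L])
  }
  list(p_estimate = ratio * p_ref, intensity_ratio = ratio,
       structure_factor_warning = has_peak)
}
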