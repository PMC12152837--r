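## Circular dichroism: normalization to molar ellipticity, Savitzky-Golay
## smoothing, chain-length-corrected helix fraction and the 222/208 nm
## coiled-coil ratio.

#' Construct a CD spectrum
#'
#' Wavelength-resolved ellipticity in millidegrees with the sample metadata
#' needed for normalization.
#'
#' @param wavelength wavelengths, nm (typically 180-400).
#' @param ellipticity ellipticity, mdeg.
#' @param concentration molar concentration of the whole molecule, mol/L.
#' @param pathlength cuvette path length, cm (0.01 mm cell = 0.001 cm).
#' @param n_residues number of peptide residues (>= 2).
#' @return an object of class `"cd_spectrum"`.
#' @export
cd_spectrum <- function(wavelength, ellipticity, concentration = NA,
                        pathlength = NA, n_residues = NA) {
  if (length(wavelength) != length(ellipticity)) {
    stop("'wavelength' and 'ellipticity' must match in length", call. = FALSE)
  }
  if (!is.na(pathlength) && pathlength <= 0) {
    stop("'pathlength' must be > 0", call. = FALSE)
  }
  if (!is.na(n_residues) && n_residues < 2) {
    stop("'n_residues' must be >= 2", call. = FALSE)
  }
  structure(list(wavelength = as.numeric(wavelength),
                 ellipticity = as.numeric(ellipticity),
                 concentration = concentration, pathlength = pathlength,
                 n_residues = as.integer(n_residues)),
            class = "cd_spectrum")
}

#' @export
print.cd_spectrum <- function(x, ...) {
  cat(sprintf("CD spectrum: %d points, %g-%g nm (c = %g M, l = %g cm, %d residues)\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              x$concentration, x$pathlength, x$n_residues))
  invisible(x)
}

#' Convert mdeg to whole-molecule molar ellipticity
#'
#' \[theta\](lambda) = theta_mdeg(lambda) / (10 c l) with c in mol/L and l in
#' cm, giving deg cm^2 dmol^-1 on a whole-molecule basis (divide by the
#' residue count afterwards for per-residue values, as [helix_fraction()]
#' does).
#'
#' @param s a [cd_spectrum()] with concentration and pathlength set.
#' @return numeric vector of molar ellipticities along `s$wavelength`.
#' @export
mdeg_to_molar_ellipticity <- function(s) {
  if (!inherits(s, "cd_spectrum")) stop("'s' must be a cd_spectrum",
                                        call. = FALSE)
  if (is.na(s$concentration) || is.na(s$pathlength)) {
    stop("concentration and pathlength must be set", call. = FALSE)
  }
  s$ellipticity / (10 * s$concentration * s$pathlength)
}

#' Theoretical per-residue helix ellipticity at 222 nm
#'
#' The chain-length-corrected 100%-helix value
#' -37400 x (1 - 2.5/n) deg cm^2 dmol^-1; the finite-chain factor accounts
#' for non-hydrogen-bonded end residues.
#'
#' @param n_residues residue count (> 2.5).
#' @return per-residue molar ellipticity, deg cm^2 dmol^-1 (negative).
#' @export
theoretical_helix_ellipticity <- function(n_residues) {
  if (any(n_residues <= 2.5)) {
    stop("'n_residues' must exceed 2.5", call. = FALSE)
  }
  -37400 * (1 - 2.5 / n_residues)
}

#' Alpha-helix fraction from the 222 nm ellipticity
#'
#' Divides the whole-molecule molar ellipticity at 222 nm by the residue
#' count and by the theoretical 100%-helix per-residue value.
#'
#' @param theta222_whole_molecule whole-molecule molar ellipticity at 222 nm,
#'   deg cm^2 dmol^-1.
#' @param n_residues residue count.
#' @param theta208_per_residue optional per-residue value at 208 nm, used to
#'   attach the coiled-coil ratio.
#' @return a list of class `"helicity_result"` with
#'   `theta222_per_residue`, `theta222_theor`, `f_a` (clipped at 1 with the
#'   raw value kept in `f_a_raw`), and when 208 nm data are given the ratio
#'   and coil classification of [coiled_coil_ratio()].
#' @export
helix_fraction <- function(theta222_whole_molecule, n_residues,
                           theta208_per_residue = NULL) {
  if (n_residues <= 0) stop("'n_residues' must be positive", call. = FALSE)
  per_res <- theta222_whole_molecule / n_residues
  theor <- theoretical_helix_ellipticity(n_residues)
  fa_raw <- per_res / theor
  out <- list(theta222_per_residue = per_res, theta222_theor = theor,
              f_a = min(fa_raw, 1), f_a_raw = fa_raw)
  if (!is.null(theta208_per_residue)) {
    cc <- coiled_coil_ratio(per_res, theta208_per_residue)
    out$ratio_222_208 <- cc$ratio
    out$coil_class <- cc$coil_class
  }
  structure(out, class = "helicity_result")
}

#' @export
print.helicity_result <- function(x, ...) {
  cat(sprintf("[theta]222 = %.1f deg cm^2/dmol per residue (theoretical 100%%: %.0f)\n",
              x$theta222_per_residue, x$theta222_theor))
  cat(sprintf("alpha-helix fraction f_a = %.3g\n", x$f_a))
  if (!is.null(x$ratio_222_208)) {
    cat(sprintf("[theta]222/[theta]208 = %.3f -> %s\n", x$ratio_222_208,
                x$coil_class))
  }
  invisible(x)
}

#' Coiled-coil indicator ratio
#'
#' ratio = \[theta\]222 / \[theta\]208; values >= 1 indicate coiled-coil
#' association of helices, < 1 isolated helices.
#'
#' @param theta222_pr,theta208_pr per-residue molar ellipticities at 222 and
#'   208 nm.
#' @return list with `ratio` and `coil_class` (`"isolated_coils"` or
#'   `"coiled_coil_indicated"`).
#' @export
coiled_coil_ratio <- function(theta222_pr, theta208_pr) {
  if (theta208_pr == 0) stop("theta208 must be nonzero", call. = FALSE)
  ratio <- theta222_pr / theta208_pr
  list(ratio = ratio,
       coil_class = if (ratio >= 1) "coiled_coil_indicated"
                    else "isolated_coils")
}

#' Savitzky-Golay smoothing of a CD spectrum
#'
#' Polynomial-preserving local least-squares smoothing of the ellipticity
#' channel; the residual (raw - smoothed) oscillates around zero for
#' noise-dominated spectra, the criterion used to choose the window.
#'
#' @param s a [cd_spectrum()].
#' @param window odd filter window length (points), >= order + 2.
#' @param order polynomial order.
#' @return the spectrum with smoothed ellipticity; the residual is attached
#'   as attribute `"residual"`.
#' @export
smooth_spectrum <- function(s, window = 9L, order = 2L) {
  if (!inherits(s, "cd_spectrum")) stop("'s' must be a cd_spectrum",
                                        call. = FALSE)
  if (window %% 2 == 0 || window < order + 2) {
    stop("'window' must be odd and >= order + 2", call. = FALSE)
  }
  if (window > length(s$ellipticity)) {
    stop("'window' larger than the spectrum", call. = FALSE)
  }
  sm <- signal::sgolayfilt(s$ellipticity, p = order, n = window)
  out <- s
  out$ellipticity <- sm
  attr(out, "residual") <- s$ellipticity - sm
  out
}

#' Read the 222 and 208 nm values and compute helicity for a spectrum
#'
#' Convenience wrapper: normalizes to molar ellipticity, interpolates 222
#' and 208 nm linearly on the wavelength grid, and returns the full
#' [helix_fraction()] result.
#'
#' @param s a [cd_spectrum()] with metadata set.
#' @param smooth logical; Savitzky-Golay smooth first (default FALSE).
#' @return a `"helicity_result"`.
#' @export
cd_helicity <- function(s, smooth = FALSE) {
  if (smooth) s <- smooth_spectrum(s)
  me <- mdeg_to_molar_ellipticity(s)
  th <- function(wl) stats::approx(s$wavelength, me, xout = wl)$y
  helix_fraction(th(222), s$n_residues,
                 theta208_per_residue = th(208) / s$n_residues)
}
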