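## Closed-form SAXS models: form factors and their combination with a
## structure factor.  All q in nm^-1, lengths in nm, electron densities in
## e/A^3, absolute intensities in cm^-1.

## --- scattering kernels ----------------------------------------------------

## sphere amplitude kernel f(x) = 3 (sin x - x cos x) / x^3, f(0) = 1.
## Series below x = 0.1 avoids the x^3 cancellation at small argument.
sphere_kernel <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 0.1
  xs <- x[small]
  out[small] <- 1 - xs^2 / 10 + xs^4 / 280 - xs^6 / 15120
  xl <- x[!small]
  out[!small] <- 3 * (sin(xl) - xl * cos(xl)) / xl^3
  out
}

## Debye kernel D(x) = 2 (exp(-x) + x - 1) / x^2, D(0) = 1; x = (q Rg)^2.
debye_kernel <- function(x) {
  out <- numeric(length(x))
  small <- x < 1e-2
  xs <- x[small]
  out[small] <- 1 - xs / 3 + xs^2 / 12 - xs^3 / 60
  xl <- x[!small]
  out[!small] <- 2 * (exp(-xl) + xl - 1) / xl^2
  out
}

## --- parameter constructors -------------------------------------------------

#' Form-factor and structure-factor parameter sets
#'
#' Lightweight validated parameter containers for the scattering models.
#' Lengths are in nm, electron densities in e/A^3, intensities in cm^-1.
#'
#' @param radius sphere radius, nm.
#' @param contrast excess electron density vs solvent, e/A^3.
#' @return a named list of class `"saxs_params"`.
#' @export
sphere_params <- function(radius, contrast = 1) {
  check_positive_scalar(radius, "radius")
  structure(list(radius = radius, contrast = contrast),
            class = c("sphere_params", "saxs_params"))
}

#' @rdname sphere_params
#' @param core_radius inner (hydrophobic core) radius R_i, nm.
#' @param outer_radius outer micelle radius R_o, nm; must exceed `core_radius`.
#' @param rho_core,rho_shell,rho_solvent electron densities, e/A^3.
#' @export
core_shell_params <- function(core_radius, outer_radius,
                              rho_core = 0.291, rho_shell = 0.40,
                              rho_solvent = 0.333) {
  check_positive_scalar(core_radius, "core_radius")
  check_positive_scalar(outer_radius, "outer_radius")
  if (core_radius >= outer_radius) {
    stop("core_radius must be smaller than outer_radius", call. = FALSE)
  }
  structure(list(core_radius = core_radius, outer_radius = outer_radius,
                 rho_core = rho_core, rho_shell = rho_shell,
                 rho_solvent = rho_solvent),
            class = c("core_shell_params", "saxs_params"))
}

#' @rdname sphere_params
#' @param rg radius of gyration of the Gaussian chain, nm.
#' @param i0 forward intensity I(0), cm^-1.
#' @export
gaussian_chain_params <- function(rg, i0) {
  check_positive_scalar(rg, "rg")
  if (!is.numeric(i0) || i0 < 0) stop("'i0' must be >= 0", call. = FALSE)
  structure(list(rg = rg, i0 = i0),
            class = c("gaussian_chain_params", "saxs_params"))
}

#' @rdname sphere_params
#' @param amplitude power-law prefactor, cm^-1 (nm^-1)^alpha.
#' @param alpha decay exponent; I(q) = amplitude * q^(-alpha).
#' @export
power_law_params <- function(amplitude, alpha) {
  if (!is.numeric(amplitude) || amplitude < 0) {
    stop("'amplitude' must be >= 0", call. = FALSE)
  }
  structure(list(amplitude = amplitude, alpha = alpha),
            class = c("power_law_params", "saxs_params"))
}

#' @rdname sphere_params
#' @param hs_radius hard-sphere (interaction) radius R_HS, nm.
#' @param volume_fraction hard-sphere volume fraction, in (0, 0.74).
#' @param z_eff effective charge modulus per particle, elementary charges.
#' @param inv_screening_length Debye screening parameter kappa, nm^-1, or
#'   `NULL` to compute it from the monovalent counterions released by the
#'   particles themselves (number density x z_eff).
#' @param temperature absolute temperature, K.
#' @param dielectric_const solvent relative dielectric constant.
#' @export
hayter_penfold_params <- function(hs_radius, volume_fraction, z_eff,
                                  inv_screening_length = NULL,
                                  temperature = 298, dielectric_const = 78.5) {
  check_positive_scalar(hs_radius, "hs_radius")
  if (!is.numeric(volume_fraction) || volume_fraction <= 0 ||
      volume_fraction >= 0.74) {
    stop("'volume_fraction' must lie in (0, 0.74)", call. = FALSE)
  }
  if (!is.numeric(z_eff) || z_eff < 0) stop("'z_eff' must be >= 0", call. = FALSE)
  if (!is.null(inv_screening_length) && inv_screening_length < 0) {
    stop("'inv_screening_length' must be >= 0", call. = FALSE)
  }
  structure(list(hs_radius = hs_radius, volume_fraction = volume_fraction,
                 z_eff = z_eff, inv_screening_length = inv_screening_length,
                 temperature = temperature, dielectric_const = dielectric_const),
            class = c("hayter_penfold_params", "saxs_params"))
}

## --- form factors -----------------------------------------------------------

#' Normalized homogeneous-sphere form factor
#'
#' P(q) = [3 (sin(qR) - qR cos(qR)) / (qR)^3]^2, normalized to 1 at q -> 0.
#'
#' @param q scattering wavenumber grid, nm^-1, strictly increasing, > 0.
#' @param params a [sphere_params()] object (or list with `radius`).
#' @return dimensionless intensity in `[0, 1]`.
#' @export
sphere_form_factor <- function(q, params) {
  check_qgrid(q)
  check_positive_scalar(params$radius, "radius")
  sphere_kernel(q * params$radius)^2
}

#' Core-shell sphere scattering amplitude and form factor
#'
#' The amplitude of a spherical core of radius R_i and electron density
#' rho_core inside a shell of outer radius R_o and density rho_shell,
#' embedded in solvent of density rho_solvent:
#' F(q) = (4 pi / 3) \[(rho_core - rho_shell) R_i^3 f(q R_i) +
#' (rho_shell - rho_solvent) R_o^3 f(q R_o)\] with
#' f(x) = 3 (sin x - x cos x) / x^3.  Radii are converted to Angstroms
#' internally so the amplitude is in electrons.
#'
#' @param q wavenumber grid, nm^-1.
#' @param params a [core_shell_params()] object.
#' @return `core_shell_amplitude`: excess-electron amplitude F(q) (e).
#' @export
core_shell_amplitude <- function(q, params) {
  check_qgrid(q)
  p <- params
  if (p$core_radius >= p$outer_radius) {
    stop("core_radius must be smaller than outer_radius", call. = FALSE)
  }
  ri <- nm_to_angstrom(p$core_radius)
  ro <- nm_to_angstrom(p$outer_radius)
  qa <- angstrom_to_nm(q)                    # nm^-1 -> A^-1
  (4 * pi / 3) * ((p$rho_core - p$rho_shell) * ri^3 * sphere_kernel(qa * ri) +
                  (p$rho_shell - p$rho_solvent) * ro^3 * sphere_kernel(qa * ro))
}

#' @rdname core_shell_amplitude
#' @param normalized logical; if `TRUE` (default) the squared amplitude is
#'   divided by its q -> 0 limit so P(0) = 1; if `FALSE` the intensity is
#'   |F(q)|^2 in electrons squared.
#' @return `core_shell_form_factor`: |F(q)|^2, normalized or not.
#' @export
core_shell_form_factor <- function(q, params, normalized = TRUE) {
  f <- core_shell_amplitude(q, params)
  if (!normalized) return(f^2)
  p <- params
  ri <- nm_to_angstrom(p$core_radius)
  ro <- nm_to_angstrom(p$outer_radius)
  f0 <- (4 * pi / 3) * ((p$rho_core - p$rho_shell) * ri^3 +
                        (p$rho_shell - p$rho_solvent) * ro^3)
  if (f0 == 0) stop("zero net contrast: cannot normalize form factor",
                    call. = FALSE)
  (f / f0)^2
}

#' Debye Gaussian-chain intensity
#'
#' I(q) = i0 * D(x), D(x) = 2 (exp(-x) + x - 1) / x^2 with x = (q Rg)^2;
#' the model for dissolved oligomers that scatter as flexible polymer coils.
#'
#' @param q wavenumber grid, nm^-1.
#' @param params a [gaussian_chain_params()] object.
#' @return intensity, cm^-1.
#' @export
gaussian_chain_intensity <- function(q, params) {
  check_qgrid(q)
  check_positive_scalar(params$rg, "rg")
  params$i0 * debye_kernel((q * params$rg)^2)
}

#' Mass-fractal power-law intensity
#'
#' I(q) = amplitude * q^(-alpha); a log-log slope of -alpha is the signature
#' of mass-fractal-like irregular aggregates.
#'
#' @param q wavenumber grid, nm^-1 (strictly positive).
#' @param params a [power_law_params()] object.
#' @return intensity, cm^-1.
#' @export
power_law_intensity <- function(q, params) {
  check_qgrid(q)
  params$amplitude * q^(-params$alpha)
}

## --- Percus-Yevick hard-sphere structure factor ----------------------------

## The three PY direct-correlation coefficients for packing fraction eta.
py_coefficients <- function(eta) {
  den <- (1 - eta)^4
  list(alpha = (1 + 2 * eta)^2 / den,
       beta  = -6 * eta * (1 + eta / 2)^2 / den,
       gamma = eta * (1 + 2 * eta)^2 / (2 * den))
}

#' Percus-Yevick hard-sphere structure factor
#'
#' Analytic S(q) for hard spheres of radius `hs_radius` at packing fraction
#' `volume_fraction`, from the closed-form PY direct correlation function.
#' Small q A = 2 q R is evaluated by series to avoid cancellation; the
#' q -> 0 limit is the PY isothermal compressibility
#' (1 - phi)^4 / (1 + 2 phi)^2.
#'
#' @param q wavenumber grid, nm^-1.
#' @param hs_radius hard-sphere radius, nm.
#' @param volume_fraction packing fraction in (0, 0.74).
#' @return structure factor S(q) > 0.
#' @export
hard_sphere_py_sf <- function(q, hs_radius, volume_fraction) {
  check_qgrid(q)
  check_positive_scalar(hs_radius, "hs_radius")
  eta <- volume_fraction
  if (!is.numeric(eta) || eta <= 0 || eta >= 0.74) {
    stop("'volume_fraction' must lie in (0, 0.74)", call. = FALSE)
  }
  co <- py_coefficients(eta)
  A <- q * 2 * hs_radius
  t1 <- t2 <- t3 <- numeric(length(A))
  small <- A < 0.25
  As <- A[small]
  t1[small] <- 1 / 3 - As^2 / 30 + As^4 / 840
  t2[small] <- 1 / 4 - As^2 / 36 + As^4 / 960
  t3[small] <- 1 / 6 - As^2 / 48
  Al <- A[!small]
  sA <- sin(Al); cA <- cos(Al)
  t1[!small] <- (sA - Al * cA) / Al^3
  t2[!small] <- (2 * Al * sA + (2 - Al^2) * cA - 2) / Al^4
  t3[!small] <- (-Al^4 * cA +
                 4 * ((3 * Al^2 - 6) * cA + (Al^3 - 6 * Al) * sA + 6)) / Al^6
  nc <- -24 * eta * (co$alpha * t1 + co$beta * t2 + co$gamma * t3)
  1 / (1 - nc)
}
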