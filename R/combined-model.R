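## Combination of a form factor with a structure factor into a model
## intensity I(q) on absolute scale.

#' Specify a combined SAXS model
#'
#' Bundles a form-factor choice, an optional interparticle structure factor,
#' an absolute-intensity scale and a flat background into a model
#' specification consumed by [combined_intensity()], [fit_saxs()] and
#' [make_saxs_curve()].
#'
#' @param form one of `"sphere"`, `"core_shell"`, `"gaussian_chain"`,
#'   `"power_law"`.
#' @param structure one of `"none"`, `"hard_sphere_py"`, `"hayter_penfold"`.
#'   Structure factors combine only with compact-particle form factors
#'   (sphere, core_shell).
#' @param scale intensity scale, cm^-1 (multiplies the normalized form
#'   factor; ignored in favour of `i0`/`amplitude` for the Gaussian-chain and
#'   power-law forms, for which it defaults to 1).
#' @param background flat incoherent background, cm^-1.
#' @param combination_mode `"product"` (I = scale P S + bkg) or
#'   `"decoupling"` (I = scale P \[1 + beta (S - 1)\] + bkg with
#'   beta = |<F>|^2 / <|F|^2>; for the monodisperse particles modelled here
#'   beta = 1 and the two modes coincide).
#' @return an object of class `"saxs_model"`.
#' @export
saxs_model <- function(form = c("sphere", "core_shell", "gaussian_chain",
                                "power_law"),
                       structure = c("none", "hard_sphere_py",
                                     "hayter_penfold"),
                       scale = 1, background = 0,
                       combination_mode = c("product", "decoupling")) {
  form <- match.arg(form)
  structure <- match.arg(structure)
  combination_mode <- match.arg(combination_mode)
  if (scale < 0) stop("'scale' must be >= 0", call. = FALSE)
  if (background < 0) stop("'background' must be >= 0", call. = FALSE)
  if (structure != "none" && form %in% c("gaussian_chain", "power_law")) {
    stop(sprintf("structure factor '%s' cannot be combined with form '%s'",
                 structure, form), call. = FALSE)
  }
  structure(list(form = form, structure = structure, scale = scale,
                 background = background, combination_mode = combination_mode),
            class = "saxs_model")
}

#' @export
print.saxs_model <- function(x, ...) {
  cat("SAXS model: form =", x$form,
      if (x$structure != "none") paste("x structure =", x$structure) else "",
      "\n  scale =", format(x$scale), "cm^-1, background =",
      format(x$background), "cm^-1, mode =", x$combination_mode, "\n")
  invisible(x)
}

form_intensity <- function(q, model, form_params) {
  switch(model$form,
    sphere = sphere_form_factor(q, form_params),
    core_shell = core_shell_form_factor(q, form_params, normalized = TRUE),
    gaussian_chain = gaussian_chain_intensity(q, form_params),
    power_law = power_law_intensity(q, form_params))
}

structure_intensity <- function(q, model, structure_params,
                                hp_control = list()) {
  switch(model$structure,
    none = rep(1, length(q)),
    hard_sphere_py = hard_sphere_py_sf(q, structure_params$hs_radius,
                                       structure_params$volume_fraction),
    hayter_penfold = hayter_penfold_sf(q, structure_params,
                                       control = hp_control))
}

#' Model intensity I(q) for a combined form/structure model
#'
#' Product mode: I(q) = scale * P(q) * S(q) + background.  Decoupling mode:
#' I(q) = scale * P(q) * \[1 + beta(q) (S(q) - 1)\] + background with
#' beta = |<F>|^2 / <|F|^2>; with no polydispersity beta(q) = 1 identically,
#' so the two modes agree for the monodisperse particles modelled here.
#'
#' @param q wavenumber grid, nm^-1.
#' @param model a [saxs_model()] specification.
#' @param form_params parameter object matching `model$form`.
#' @param structure_params parameter object matching `model$structure`
#'   ([hayter_penfold_params()], or a list with `hs_radius` and
#'   `volume_fraction` for the Percus-Yevick option).
#' @param hp_control optional solver control list forwarded to
#'   [hayter_penfold_sf()].
#' @return intensity, cm^-1.
#' @export
combined_intensity <- function(q, model, form_params,
                               structure_params = NULL,
                               hp_control = list()) {
  check_qgrid(q)
  if (!inherits(model, "saxs_model")) stop("'model' must be a saxs_model",
                                           call. = FALSE)
  P <- form_intensity(q, model, form_params)
  if (model$structure == "none") {
    return(model$scale * P + model$background)
  }
  if (is.null(structure_params)) {
    stop("structure_params required for structure factor ", model$structure,
         call. = FALSE)
  }
  S <- structure_intensity(q, model, structure_params, hp_control)
  beta <- 1  # monodisperse amplitude-decoupling factor
  S_eff <- switch(model$combination_mode,
                  product = S,
                  decoupling = 1 + beta * (S - 1))
  model$scale * P * S_eff + model$background
}
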