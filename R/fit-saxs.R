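## Weighted nonlinear least-squares fitting of scattering curves to combined
## models, with Latin-hypercube multi-start and a classed fit object.

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
              rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

## parameter vector <-> parameter objects -----------------------------------

## outer_radius is fitted through shell_thickness = R_o - R_i so the
## R_i < R_o constraint is a simple positivity bound.
flatten_params <- function(model, form_params, structure_params) {
  fp <- switch(model$form,
    sphere = c(radius = form_params$radius),
    core_shell = c(core_radius = form_params$core_radius,
                   shell_thickness = form_params$outer_radius -
                                     form_params$core_radius,
                   rho_core = form_params$rho_core,
                   rho_shell = form_params$rho_shell),
    gaussian_chain = c(rg = form_params$rg, i0 = form_params$i0),
    power_law = c(amplitude = form_params$amplitude,
                  alpha = form_params$alpha))
  sp <- switch(model$structure,
    none = c(),
    hard_sphere_py = c(hs_radius = structure_params$hs_radius,
                       volume_fraction = structure_params$volume_fraction),
    hayter_penfold = c(hs_radius = structure_params$hs_radius,
                       volume_fraction = structure_params$volume_fraction,
                       z_eff = structure_params$z_eff))
  c(fp, sp, scale = model$scale, background = model$background)
}

unflatten_params <- function(theta, model, form_params, structure_params) {
  g <- function(nm, default) if (nm %in% names(theta)) theta[[nm]] else default
  fp <- form_params
  if (model$form == "sphere") {
    fp$radius <- g("radius", fp$radius)
  } else if (model$form == "core_shell") {
    fp$core_radius <- g("core_radius", fp$core_radius)
    st <- g("shell_thickness", fp$outer_radius - fp$core_radius)
    fp$outer_radius <- fp$core_radius + st
    fp$rho_core <- g("rho_core", fp$rho_core)
    fp$rho_shell <- g("rho_shell", fp$rho_shell)
  } else if (model$form == "gaussian_chain") {
    fp$rg <- g("rg", fp$rg); fp$i0 <- g("i0", fp$i0)
  } else {
    fp$amplitude <- g("amplitude", fp$amplitude)
    fp$alpha <- g("alpha", fp$alpha)
  }
  sp <- structure_params
  if (model$structure != "none") {
    sp$hs_radius <- g("hs_radius", sp$hs_radius)
    sp$volume_fraction <- g("volume_fraction", sp$volume_fraction)
    if (model$structure == "hayter_penfold") sp$z_eff <- g("z_eff", sp$z_eff)
  }
  m <- model
  m$scale <- g("scale", m$scale)
  m$background <- g("background", m$background)
  list(model = m, form_params = fp, structure_params = sp)
}

default_free <- function(model) {
  fp <- switch(model$form,
    sphere = c("radius", "scale"),
    core_shell = c("core_radius", "shell_thickness", "scale"),
    gaussian_chain = c("rg", "i0"),
    power_law = c("amplitude", "alpha"))
  sp <- switch(model$structure,
    none = character(),
    hard_sphere_py = c("hs_radius", "volume_fraction"),
    hayter_penfold = c("hs_radius", "volume_fraction", "z_eff"))
  c(fp, sp)
}

default_bounds <- function(free, init) {
  lower <- upper <- numeric(length(free))
  names(lower) <- names(upper) <- free
  for (nm in free) {
    x0 <- init[[nm]]
    bd <- switch(nm,
      radius = , core_radius = , shell_thickness = , hs_radius =
        c(0.1, 20),
      rg = c(0.05, 50),
      rho_core = , rho_shell = c(0.1, 0.6),
      volume_fraction = c(1e-4, 0.5),
      z_eff = c(0, 40),
      alpha = c(0, 6),
      background = c(0, max(1e-6, 100 * abs(x0))),
      ## intensity-like scales: wide relative bounds
      c(max(1e-12, abs(x0) / 100), max(1e-8, abs(x0) * 100)))
    lower[nm] <- bd[1]; upper[nm] <- bd[2]
  }
  list(lower = lower, upper = upper)
}

#' Fit a combined SAXS model to a scattering curve
#'
#' Minimizes the sigma-weighted sum of squares
#' sum(\[(I_obs - I_model)/sigma\]^2) with Levenberg-Marquardt
#' (\pkg{minpack.lm}), restarted from a seeded Latin-hypercube of initial
#' values over the parameter bounds; the best converged start is returned.
#' Curves without uncertainties are fitted unweighted with a warning.
#'
#' @param curve a [saxs_curve()] with at least 10 points.
#' @param model a [saxs_model()]; its `scale`/`background` are initial
#'   values.
#' @param form_params,structure_params initial parameter objects.
#' @param free character vector of parameter names to vary; defaults to the
#'   natural free set of the model (`outer_radius` is fitted as
#'   `shell_thickness = R_o - R_i` so the ordering constraint is a bound).
#' @param lower,upper optional named bounds overriding the defaults.
#' @param n_starts number of multi-start initializations (the supplied
#'   initial values are always start 1).
#' @param seed integer seed making the Latin-hypercube starts reproducible.
#' @param hp_control Hayter-Penfold solver settings used during fitting; the
#'   default coarsens the solver grid (ample for fitting noisy data) and
#'   caps the contact coupling at 40 kT so the optimizer cannot wander into
#'   expensive unphysical strong-coupling corners (such trial points score
#'   as misfits).
#' @param lm_control a [minpack.lm::nls.lm.control()] list bounding the
#'   optimizer effort per start.
#' @param tie_hs_radius logical; for core-shell + structure-factor models,
#'   constrain the structure-factor hard-sphere radius to equal the
#'   form-factor outer radius (the micelle interaction radius), removing a
#'   poorly determined degeneracy direction from the fit.
#' @return an object of class `"saxs_fit"` with methods `print`, `summary`,
#'   `coef`, `vcov`, `predict`, `fitted`, `residuals`, `plot` and
#'   `simulate`.  `converged = FALSE` flags an unconverged fit; no exception
#'   is thrown for that.
#' @export
fit_saxs <- function(curve, model, form_params, structure_params = NULL,
                     free = NULL, lower = NULL, upper = NULL,
                     n_starts = 8L, seed = 20250512L,
                     hp_control = list(n_grid = 2048L, j_core = 128L,
                                       max_gamma = 40, maxit = 1000L),
                     lm_control = minpack.lm::nls.lm.control(
                       maxiter = 60, maxfev = 400),
                     tie_hs_radius = FALSE) {
  if (!inherits(curve, "saxs_curve")) stop("'curve' must be a saxs_curve",
                                           call. = FALSE)
  if (nrow(curve) < 10L) stop("need at least 10 data points", call. = FALSE)
  if (any(!is.finite(curve$intensity))) stop("NaN in intensity data",
                                             call. = FALSE)
  weighted <- !is.null(curve$sigma)
  if (!weighted) warning("curve carries no uncertainties: unweighted fit")
  w <- if (weighted) 1 / curve$sigma else rep(1, nrow(curve))

  tie_hs_radius <- tie_hs_radius && model$structure != "none" &&
                   model$form == "core_shell"
  init_all <- flatten_params(model, form_params, structure_params)
  if (is.null(free)) free <- default_free(model)
  if (tie_hs_radius) free <- setdiff(free, "hs_radius")
  if (!all(free %in% names(init_all))) {
    stop("unknown free parameter(s): ",
         paste(setdiff(free, names(init_all)), collapse = ", "),
         call. = FALSE)
  }
  bd <- default_bounds(free, init_all)
  if (!is.null(lower)) {
    nm <- intersect(names(lower), free)
    bd$lower[nm] <- lower[nm]
  }
  if (!is.null(upper)) {
    nm <- intersect(names(upper), free)
    bd$upper[nm] <- upper[nm]
  }
  if (any(bd$lower >= bd$upper)) stop("inconsistent bounds", call. = FALSE)

  q <- curve$q
  model_eval <- function(theta) {
    pp <- unflatten_params(as.list(theta), model, form_params,
                           structure_params)
    if (tie_hs_radius) pp$structure_params$hs_radius <- pp$form_params$outer_radius
    tryCatch(combined_intensity(q, pp$model, pp$form_params,
                                pp$structure_params, hp_control = hp_control),
             error = function(e) NULL)
  }
  resid_fn <- function(theta) {
    names(theta) <- free
    I <- model_eval(theta)
    if (is.null(I) || any(!is.finite(I))) {
      return(rep(1e6, nrow(curve)))
    }
    (I - curve$intensity) * w
  }

  starts <- matrix(init_all[free], nrow = 1,
                   dimnames = list(NULL, free))
  if (n_starts > 1L) {
    u <- with_local_seed(seed, lhs::randomLHS(n_starts - 1L, length(free)))
    extra <- sweep(u, 2, bd$upper - bd$lower, `*`)
    extra <- sweep(extra, 2, bd$lower, `+`)
    colnames(extra) <- free
    starts <- rbind(starts, extra)
  }
  starts <- pmin(pmax(starts, rep(bd$lower, each = nrow(starts))),
                 rep(bd$upper, each = nrow(starts)))

  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit_k <- tryCatch(
      minpack.lm::nls.lm(par = starts[k, ], lower = bd$lower,
                         upper = bd$upper, fn = resid_fn,
                         control = lm_control),
      error = function(e) NULL)
    if (is.null(fit_k)) next
    if (is.null(best) || fit_k$deviance < best$deviance) best <- fit_k
  }

  n_free <- length(free)
  dof <- nrow(curve) - n_free
  if (is.null(best)) {
    res <- structure(list(best_params = init_all[free], se = rep(NA_real_,
                                                                 n_free),
                          chi2_reduced = NA_real_, n_points = nrow(curve),
                          converged = FALSE, weighted = weighted,
                          model = model, form_params = form_params,
                          structure_params = structure_params, free = free,
                          curve = curve, model_id = paste(model$form,
                                                          model$structure,
                                                          sep = "+")),
                     class = "saxs_fit")
    return(res)
  }
  theta <- stats::setNames(best$par, free)
  chi2_red <- best$deviance / max(dof, 1L)
  vc <- tryCatch({
    h <- solve(best$hessian)
    2 * chi2_red * h
  }, error = function(e) matrix(NA_real_, n_free, n_free))
  se <- sqrt(pmax(diag(vc), 0))
  pp <- unflatten_params(as.list(theta), model, form_params, structure_params)
  if (tie_hs_radius) pp$structure_params$hs_radius <- pp$form_params$outer_radius
  structure(list(best_params = theta, se = stats::setNames(se, free),
                 vcov = vc, chi2_reduced = chi2_red, n_points = nrow(curve),
                 converged = best$info %in% 1:3, info = best$info,
                 weighted = weighted, model = pp$model,
                 form_params = pp$form_params,
                 structure_params = pp$structure_params, free = free,
                 curve = curve,
                 model_id = paste(model$form, model$structure, sep = "+")),
            class = "saxs_fit")
}

## --- methods ----------------------------------------------------------------

#' @export
coef.saxs_fit <- function(object, ...) object$best_params

#' @export
vcov.saxs_fit <- function(object, ...) object$vcov

#' @export
predict.saxs_fit <- function(object, q = NULL, ...) {
  if (is.null(q)) q <- object$curve$q
  combined_intensity(q, object$model, object$form_params,
                     object$structure_params)
}

#' @export
fitted.saxs_fit <- function(object, ...) predict(object)

#' @export
residuals.saxs_fit <- function(object, type = c("weighted", "raw"), ...) {
  type <- match.arg(type)
  r <- object$curve$intensity - fitted(object)
  if (type == "weighted" && !is.null(object$curve$sigma)) {
    r <- r / object$curve$sigma
  }
  r
}

#' @export
print.saxs_fit <- function(x, ...) {
  cat(sprintf("SAXS fit [%s]%s: chi2_red = %.4g on %d points%s\n",
              x$model_id, if (x$weighted) "" else " (unweighted)",
              x$chi2_reduced, x$n_points,
              if (x$converged) "" else "  ** NOT CONVERGED **"))
  print(round(x$best_params, 6))
  invisible(x)
}

#' @export
summary.saxs_fit <- function(object, ...) {
  tab <- data.frame(estimate = object$best_params,
                    std_error = object$se, row.names = object$free)
  out <- list(table = tab, chi2_reduced = object$chi2_reduced,
              converged = object$converged, model_id = object$model_id,
              n_points = object$n_points)
  class(out) <- "summary.saxs_fit"
  out
}

#' @export
print.summary.saxs_fit <- function(x, ...) {
  cat(sprintf("Model: %s  (%d points, chi2_red = %.4g, converged: %s)\n",
              x$model_id, x$n_points, x$chi2_reduced, x$converged))
  print(x$table)
  invisible(x)
}

#' @export
plot.saxs_fit <- function(x, ...) {
  plot(x$curve, ...)
  graphics::lines(x$curve$q, fitted(x), col = 2, lwd = 2)
  invisible(x)
}

#' @export
simulate.saxs_fit <- function(object, nsim = 1, seed = NULL, ...) {
  I <- fitted(object)
  s <- if (!is.null(object$curve$sigma)) object$curve$sigma else 0.02 * I
  gen <- function() saxs_curve(object$curve$q, I + stats::rnorm(length(I),
                                                                sd = s),
                               sigma = s,
                               concentration = attr(object$curve,
                                                    "concentration"))
  if (!is.null(seed)) with_local_seed(seed, replicate(nsim, gen(),
                                                      simplify = FALSE))
  else replicate(nsim, gen(), simplify = FALSE)
}

#' Compare charged-sphere and plain hard-sphere structure-factor fits
#'
#' Fits the same core-shell form factor combined with (a) the
#' Hayter-Penfold charged-sphere structure factor and (b) the plain
#' Percus-Yevick hard-sphere structure factor, and reports both fits and
#' their reduced-chi-square ratio.  A flat, peakless curve yields flagged
#' (unconverged or peakless) results rather than an error.
#'
#' @param curve a [saxs_curve()] with a resolvable interference peak.
#' @param form_params initial [core_shell_params()].
#' @param structure_params initial [hayter_penfold_params()].
#' @param ... passed to [fit_saxs()] (e.g. `n_starts`, `seed`).
#' @return list with `fit_hp`, `fit_py`, `chi2_ratio`
#'   (HP chi2_red / PY chi2_red) and `peakless`.
#' @export
compare_structure_factors <- function(curve, form_params, structure_params,
                                      ...) {
  ii <- curve$intensity
  n <- length(ii)
  peakless <- TRUE
  if (n > 14L) {
    m <- 7:(n - 7L)
    peakless <- !any(ii[m] > 1.03 * ii[m - 6L] & ii[m] > 1.03 * ii[m + 6L])
  }
  model_hp <- saxs_model("core_shell", "hayter_penfold", scale = 1)
  model_py <- saxs_model("core_shell", "hard_sphere_py", scale = 1)
  sp_py <- list(hs_radius = structure_params$hs_radius,
                volume_fraction = structure_params$volume_fraction)
  fit_hp <- fit_saxs(curve, model_hp, form_params, structure_params, ...)
  fit_py <- fit_saxs(curve, model_py, form_params, sp_py, ...)
  list(fit_hp = fit_hp, fit_py = fit_py,
       chi2_ratio = fit_hp$chi2_reduced / fit_py$chi2_reduced,
       peakless = peakless)
}
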