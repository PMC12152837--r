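## ScatteringCurve container.

#' Construct a scattering curve
#'
#' A measured or synthetic SAXS profile: wavenumber q (nm^-1), absolute
#' intensity (cm^-1) and optional 1-sigma uncertainties, plus sample
#' metadata.
#'
#' @param q strictly increasing wavenumber grid, nm^-1.
#' @param intensity intensity, cm^-1.
#' @param sigma optional 1-sigma uncertainty per point, cm^-1, all > 0.
#' @param concentration optional sample mass concentration, g cm^-3.
#' @param label optional text label.
#' @return an object of class `"saxs_curve"` (a data frame with columns
#'   `q`, `intensity` and, when present, `sigma`, plus attributes).
#' @export
saxs_curve <- function(q, intensity, sigma = NULL, concentration = NULL,
                       label = "") {
  check_qgrid(q)
  if (length(intensity) != length(q)) {
    stop("'q' and 'intensity' must have equal length", call. = FALSE)
  }
  if (any(!is.finite(intensity))) {
    stop("'intensity' contains non-finite values", call. = FALSE)
  }
  if (!is.null(sigma)) {
    if (length(sigma) != length(q)) {
      stop("'sigma' must match 'q' in length", call. = FALSE)
    }
    if (any(!is.finite(sigma)) || any(sigma <= 0)) {
      stop("'sigma' must be positive and finite where present", call. = FALSE)
    }
  }
  df <- data.frame(q = q, intensity = intensity)
  if (!is.null(sigma)) df$sigma <- sigma
  structure(df, class = c("saxs_curve", "data.frame"),
            concentration = concentration, label = label)
}

#' @export
print.saxs_curve <- function(x, ...) {
  lab <- attr(x, "label")
  conc <- attr(x, "concentration")
  cat("SAXS curve", if (nzchar(lab)) sprintf("'%s'", lab) else "",
      sprintf("(%d points, q = %.4g-%.4g nm^-1%s%s)\n", nrow(x), min(x$q),
              max(x$q),
              if (is.null(x$sigma)) ", unweighted" else "",
              if (!is.null(conc)) sprintf(", c = %g g/cm^3", conc) else ""))
  invisible(x)
}

#' @export
plot.saxs_curve <- function(x, ..., log = "xy") {
  graphics::plot(x$q, x$intensity, log = log, xlab = expression(q ~ (nm^-1)),
                 ylab = expression(I(q) ~ (cm^-1)), ...)
  if (!is.null(x$sigma)) {
    graphics::segments(x$q, x$intensity - x$sigma, x$q, x$intensity + x$sigma)
  }
  invisible(x)
}
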