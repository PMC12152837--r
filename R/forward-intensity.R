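## Model-independent forward scattering I(0), power-law exponent and
## CMC breakpoint estimation.

#' Forward scattering intensity I(0)
#'
#' Guinier method: iterated weighted fit of ln I vs q^2 restricted to the
#' window q*Rg <= 1.3 (two passes: an initial fit on the lowest-q points
#' sets Rg, the window is re-selected and the fit repeated).  Plateau
#' method: uncertainty-weighted mean over the lowest-q decade
#' (q <= 10 q_min), appropriate when the curve is flat at low q.
#'
#' @param curve a [saxs_curve()].
#' @param method `"guinier"` or `"plateau"`.
#' @param qrg_max Guinier window limit on q*Rg (default 1.3).
#' @return list with `i0`, `se`, `method`, and for Guinier also `rg` (nm)
#'   and `n_used`.
#' @export
forward_intensity <- function(curve, method = c("guinier", "plateau"),
                              qrg_max = 1.3) {
  method <- match.arg(method)
  q <- curve$q; I <- curve$intensity
  if (method == "plateau") {
    sel <- q <= 10 * min(q)
    if (sum(sel) < 5L) stop("fewer than 5 points in the lowest-q decade",
                            call. = FALSE)
    if (!is.null(curve$sigma)) {
      w <- 1 / curve$sigma[sel]^2
      i0 <- sum(w * I[sel]) / sum(w)
      se <- sqrt(1 / sum(w))
    } else {
      i0 <- mean(I[sel])
      se <- stats::sd(I[sel]) / sqrt(sum(sel))
    }
    return(list(i0 = i0, se = se, method = "plateau", n_used = sum(sel)))
  }
  ## Guinier: ln I = ln I0 - (q Rg)^2 / 3
  usable <- I > 0
  if (sum(usable) < 5L) stop("fewer than 5 usable low-q points",
                             call. = FALSE)
  sel <- usable & seq_along(q) <= max(10L, ceiling(sum(usable) / 4))
  for (pass in 1:2) {
    if (sum(sel) < 5L) stop("fewer than 5 points in the Guinier window",
                            call. = FALSE)
    y <- log(I[sel])
    w <- if (!is.null(curve$sigma)) (I[sel] / curve$sigma[sel])^2
         else rep(1, sum(sel))
    fit <- stats::lm(y ~ I(q[sel]^2), weights = w)
    slope <- stats::coef(fit)[[2]]
    rg <- if (slope < 0) sqrt(-3 * slope) else 0
    if (rg > 0) sel <- usable & q * rg <= qrg_max
  }
  sm <- summary(fit)
  i0 <- exp(stats::coef(fit)[[1]])
  list(i0 = i0, se = i0 * sm$coefficients[1, 2], rg = rg,
       method = "guinier", n_used = sum(sel))
}

#' Power-law decay exponent
#'
#' Weighted linear regression of log I on log q over the chosen q range;
#' the exponent alpha of I(q) ~ q^-alpha is minus the slope.
#'
#' @param curve a [saxs_curve()].
#' @param q_range length-2 numeric q window, nm^-1 (default: full range).
#' @return list with `alpha`, `se` and `n_used`.
#' @export
powerlaw_exponent <- function(curve, q_range = range(curve$q)) {
  sel <- curve$q >= q_range[1] & curve$q <= q_range[2]
  if (sum(sel) < 5L) stop("need at least 5 points in the q range",
                          call. = FALSE)
  I <- curve$intensity[sel]
  if (any(I <= 0)) stop("nonpositive intensities in the fit range",
                        call. = FALSE)
  x <- log(curve$q[sel]); y <- log(I)
  w <- if (!is.null(curve$sigma)) (I / curve$sigma[sel])^2 else rep(1, sum(sel))
  fit <- stats::lm(y ~ x, weights = w)
  list(alpha = -stats::coef(fit)[[2]],
       se = summary(fit)$coefficients[2, 2], n_used = sum(sel))
}

#' Two-segment breakpoint (CMC) fit
#'
#' Continuous piecewise-linear least squares in log10 of the abscissa:
#' y = b0 + b1 u + b2 (u - k)+ with u = log10(x).  The knot k is located by
#' a grid search over interior positions followed by golden-section
#' refinement of the profile RSS; significance of the break against a
#' single straight line is assessed with an F-test (2 extra parameters) at
#' alpha = 0.05.  The breakpoint uncertainty comes from the curvature of
#' the RSS profile at the optimum.
#'
#' @param x concentrations (or any positive abscissa), length >= 6.
#' @param y responses.
#' @param alpha significance level for the F-test.
#' @return an object of class `"breakpoint_result"`: list with `breakpoint`
#'   (same units as `x`), `slopes` (left/right, per decade),
#'   `breakpoint_uncertainty`, `significant`, `p_value`, `rss`.
#' @export
breakpoint_fit <- function(x, y, alpha = 0.05) {
  if (length(x) < 6L || length(y) != length(x)) {
    stop("need >= 6 (x, y) points", call. = FALSE)
  }
  if (any(x <= 0)) stop("'x' must be positive", call. = FALSE)
  o <- order(x)
  u <- log10(x[o]); yy <- y[o]
  n <- length(u)

  rss_at <- function(k) {
    X <- cbind(1, u, pmax(u - k, 0))
    f <- stats::lm.fit(X, yy)
    sum(f$residuals^2)
  }
  ## interior knots: keep at least 2 points strictly on each side
  klo <- u[2]; khi <- u[n - 1]
  grid <- seq(klo, khi, length.out = 201)
  rss_g <- vapply(grid, rss_at, numeric(1))
  k0 <- grid[which.min(rss_g)]
  span <- diff(range(grid)) / 200
  opt <- stats::optimize(rss_at, lower = max(klo, k0 - 2 * span),
                         upper = min(khi, k0 + 2 * span), tol = 1e-9)
  k_hat <- opt$minimum
  rss1 <- opt$objective
  fit1 <- stats::lm.fit(cbind(1, u, pmax(u - k_hat, 0)), yy)
  b <- fit1$coefficients
  fit0 <- stats::lm.fit(cbind(1, u), yy)
  rss0 <- sum(fit0$residuals^2)

  dof <- n - 4L
  sigma2 <- rss1 / dof
  collinear <- rss0 <= max(1e-25, 1e-12 * sum(yy^2))
  if (collinear || rss1 >= rss0) {
    return(structure(list(breakpoint = NA_real_,
                          slopes = c(left = b[[2]], right = b[[2]] + b[[3]]),
                          breakpoint_uncertainty = NA_real_,
                          significant = FALSE, p_value = 1, rss = rss1),
                     class = "breakpoint_result"))
  }
  Fstat <- ((rss0 - rss1) / 2) / sigma2
  p <- stats::pf(Fstat, 2, dof, lower.tail = FALSE)

  ## curvature of the RSS profile -> knot standard error
  h <- max(1e-4, span / 10)
  d2 <- (rss_at(k_hat + h) - 2 * rss1 + rss_at(k_hat - h)) / h^2
  se_log <- if (is.finite(d2) && d2 > 0) sqrt(2 * sigma2 / d2) else NA_real_
  bp <- 10^k_hat
  structure(list(breakpoint = bp,
                 slopes = c(left = b[[2]], right = b[[2]] + b[[3]]),
                 breakpoint_uncertainty = if (is.na(se_log)) NA_real_
                                          else bp * log(10) * se_log,
                 significant = p < alpha, p_value = p, rss = rss1),
            class = "breakpoint_result")
}

#' @export
print.breakpoint_result <- function(x, ...) {
  if (is.na(x$breakpoint)) {
    cat("No significant breakpoint (data consistent with a single line)\n")
  } else {
    cat(sprintf("Breakpoint at %.4g (+/- %.2g), slopes %.3g -> %.3g, p = %.3g%s\n",
                x$breakpoint, x$breakpoint_uncertainty, x$slopes[1],
                x$slopes[2], x$p_value,
                if (x$significant) "" else " (not significant)"))
  }
  invisible(x)
}
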