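## Independent numerical oracles used to freeze expected values.
## These deliberately share no code with the package implementation.

## ---- real-space Ornstein-Zernike / MSA oracle ------------------------------
## Iterative solution on a midpoint r-grid using the bipolar convolution
## kernel (no Fourier transforms, no Anderson acceleration).  Reduced units
## x = r/sigma.  Returns S on a Q grid plus the contact value g(1+).
oz_msa_oracle_raw <- function(eta, k, gamma, M = 700, r_max = 14,
                              n_iter = 400, mix = 0.3, depth = 10L) {
  dr <- r_max / M
  r <- (seq_len(M) - 0.5) * dr
  rho <- 6 * eta / pi
  inside <- r < 1
  c_out <- -gamma * exp(-k * (r - 1)) / r
  nin <- sum(inside)
  ## unknowns: u = (c inside, h outside); fixed-point map from one OZ
  ## convolution step via the bipolar kernel
  fp <- function(u) {
    cvec <- ifelse(inside, NA_real_, c_out)
    cvec[inside] <- u[seq_len(nin)]
    hvec <- ifelse(inside, -1, NA_real_)
    hvec[!inside] <- u[(nin + 1):M]
    Tcum <- c(0, cumsum(r * hvec * dr))
    Tfun <- function(x) {
      x <- pmin(x, r_max)
      i <- pmin(M, pmax(0, floor(x / dr)))
      frac <- x / dr - i
      lo <- Tcum[i + 1]
      hi <- Tcum[pmin(M, i) + 1 + (i < M)]
      lo + frac * (hi - lo) * (i < M)
    }
    inner <- matrix(Tfun(outer(r, r, `+`)), M) -
             matrix(Tfun(abs(outer(r, r, `-`))), M)
    gam_r <- 2 * pi * rho / r * drop(inner %*% (r * cvec * dr))
    c(-1 - gam_r[inside], c_out[!inside] + gam_r[!inside])
  }
  u <- c(rep(-1, nin), rep(0, M - nin))
  dP <- dR <- NULL; u_prev <- res_prev <- NULL
  converged <- FALSE
  for (it in seq_len(n_iter)) {
    f_val <- fp(u)
    res <- f_val - u
    err <- max(abs(res))
    if (!is.finite(err)) stop("oracle iteration blew up")
    if (err < 1e-10) { converged <- TRUE; break }
    if (!is.null(res_prev)) {
      dP <- cbind(dP, u - u_prev); dR <- cbind(dR, res - res_prev)
      if (ncol(dP) > depth) { dP <- dP[, -1, drop = FALSE]
                              dR <- dR[, -1, drop = FALSE] }
    }
    u_prev <- u; res_prev <- res
    if (is.null(dR)) {
      u <- u + mix * res
    } else {
      gam <- qr.coef(qr(dR), res)
      gam[!is.finite(gam)] <- 0
      u <- u + mix * res - (dP + mix * dR) %*% gam
      u <- drop(u)
    }
  }
  if (!converged) warning("OZ oracle not fully converged: err ~ ", err)
  cvec <- ifelse(inside, NA_real_, c_out); cvec[inside] <- u[seq_len(nin)]
  hvec <- ifelse(inside, -1, NA_real_);   hvec[!inside] <- u[(nin + 1):M]
  ## contact value from just outside the core
  oj <- which(!inside)[1:5]
  cf <- stats::lm.fit(cbind(1, r[oj] - 1), 1 + hvec[oj])$coefficients
  list(S = function(Q) {
    vapply(Q, function(qq) {
      s <- if (qq < 1e-8) rep(1, M) else sin(qq * r) / (qq * r)
      1 + rho * 4 * pi * sum(r^2 * hvec * s * dr)
    }, numeric(1))
  }, g_contact = cf[[1]])
}

## Hansen-Hayter rescaling applied on top of the raw oracle (independent
## re-implementation of the same physical prescription).
oz_msa_oracle <- function(hs_radius, volume_fraction, z_eff, kappa,
                          temperature = 298, dielectric_const = 78.5, ...) {
  sigma <- 2 * hs_radius
  lb <- bjerrum_length(temperature, dielectric_const)
  gamma0 <- z_eff^2 * lb / (sigma * (1 + kappa * sigma / 2)^2)
  solve_s <- function(s) {
    oz_msa_oracle_raw(s^3 * volume_fraction, kappa * sigma * s,
                      gamma0 * exp(-kappa * sigma * (s - 1)) / s, ...)
  }
  sol <- solve_s(1)
  s_star <- 1
  if (gamma0 > 0 && sol$g_contact < 0) {
    s_hi <- 1
    repeat {
      s_hi <- s_hi * 1.2
      if (solve_s(s_hi)$g_contact >= 0 || s_hi > 4) break
    }
    s_star <- stats::uniroot(function(s) solve_s(s)$g_contact,
                             lower = s_hi / 1.2, upper = s_hi,
                             tol = 1e-5)$root
    sol <- solve_s(s_star)
  }
  function(q) sol$S(q * sigma * s_star)
}

## ---- core-shell quadrature oracle ------------------------------------------
## Fourier transform of the radial excess-density profile by numerical
## quadrature (Angstrom units; amplitude in electrons).
core_shell_quadrature <- function(q_nm, p) {
  ri <- p$core_radius * 10; ro <- p$outer_radius * 10
  vapply(q_nm / 10, function(qa) {
    f <- function(r) {
      drho <- ifelse(r <= ri, p$rho_core - p$rho_solvent,
                     p$rho_shell - p$rho_solvent)
      if (qa < 1e-12) 4 * pi * r^2 * drho
      else 4 * pi * r^2 * drho * sin(qa * r) / (qa * r)
    }
    stats::integrate(f, 0, ri, rel.tol = 1e-12)$value +
      stats::integrate(f, ri, ro, rel.tol = 1e-12)$value
  }, numeric(1))
}

## ---- Monte-Carlo SASA oracle -----------------------------------------------
## Random-direction sphere sampling at high point count (independent of the
## deterministic Fibonacci lattice used by the implementation).
sasa_mc_oracle <- function(cs, probe = 0.14, n = 20000L, seed = 99L) {
  set.seed(seed)
  pos <- cs$positions
  rad <- cs$radii + probe
  natom <- nrow(pos)
  total <- 0
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  pts <- cbind(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
  for (i in seq_len(natom)) {
    dc2 <- rowSums(sweep(pos, 2, pos[i, ])^2)
    nb <- which(dc2 < (rad + rad[i])^2 & seq_len(natom) != i)
    sp <- sweep(pts * rad[i], 2, pos[i, ], `+`)
    exposed <- rep(TRUE, n)
    for (j in nb) {
      d2 <- (sp[, 1] - pos[j, 1])^2 + (sp[, 2] - pos[j, 2])^2 +
            (sp[, 3] - pos[j, 3])^2
      exposed <- exposed & d2 > rad[j]^2
    }
    total <- total + 4 * pi * rad[i]^2 * mean(exposed)
  }
  total
}

## convenience: random rigid rotation matrix
random_rotation <- function(seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(9), 3)
  qr.Q(qr(m)) * sign(det(qr.Q(qr(m))))
}
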