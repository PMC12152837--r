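## Seeded generators for every input the analysis pipeline consumes:
## SAXS curves (dilute oligomer, concentrated micellar, fractal), CD
## spectra, micelle coordinate sets and fluorescence titrations.

default_qgrid <- function(n = 150, qmin = 0.05, qmax = 5) {
  exp(seq(log(qmin), log(qmax), length.out = n))
}

#' Generate a synthetic SAXS curve
#'
#' Evaluates a combined model on a q grid and adds multiplicative Gaussian
#' noise with an absolute floor, emulating photon-statistics-dominated
#' synchrotron curves: sigma(q) = relative_sd * I_model(q) + floor and
#' I_obs = I_model + N(0, sigma).  Deterministic for a fixed seed.
#'
#' @param model a [saxs_model()].
#' @param form_params,structure_params model parameter objects.
#' @param q wavenumber grid, nm^-1.
#' @param relative_sd relative noise level (0.02 = 2%).
#' @param floor absolute noise floor, cm^-1.
#' @param seed integer seed.
#' @param concentration sample concentration recorded in the curve
#'   metadata, g cm^-3.
#' @param label curve label.
#' @return a [saxs_curve()] with sigma column.
#' @export
make_saxs_curve <- function(model, form_params, structure_params = NULL,
                            q = default_qgrid(), relative_sd = 0.02,
                            floor = 0, seed = 1L, concentration = NULL,
                            label = "synthetic") {
  I <- combined_intensity(q, model, form_params, structure_params)
  s <- relative_sd * abs(I) + floor
  I_obs <- if (all(s == 0)) I else {
    with_local_seed(seed, I + stats::rnorm(length(I), sd = s))
  }
  saxs_curve(q, I_obs, sigma = if (all(s == 0)) NULL else s,
             concentration = concentration, label = label)
}

#' Bundled generation presets for the study conditions
#'
#' Named parameter bundles reproducing the three scattering regimes of
#' aqueous semaglutide: `"dilute_0.1wt"` - aged dilute solution, small
#' oligomers scattering as Gaussian chains with I(0) = 0.0025 cm^-1 at
#' c = 0.001 g/cm^3; `"aged_1wt"` - aged concentrated solution, core-shell
#' micelles (R_i = 1.5 nm, R_o = 2.45 nm) with the charged-sphere structure
#' factor (z_eff = 10.8, R_HS = 2.45 nm, phi = c v_p = 0.0117), showing the
#' interference peak at q = 0.4-0.5 nm^-1; `"fractal_fresh"` - freshly
#' dissolved solution with mass-fractal low-q scaling I ~ q^-2.6.
#'
#' @param name preset name.
#' @return list with `model`, `form_params`, `structure_params`,
#'   `concentration` and a default `q` grid, ready for
#'   [make_saxs_curve()].
#' @export
saxs_preset <- function(name = c("dilute_0.1wt", "aged_1wt",
                                 "fractal_fresh")) {
  name <- match.arg(name)
  switch(name,
    dilute_0.1wt = list(
      model = saxs_model("gaussian_chain"),
      form_params = gaussian_chain_params(rg = 1.6, i0 = 0.0025),
      structure_params = NULL,
      concentration = 0.001,
      q = default_qgrid(120, 0.05, 3)),
    aged_1wt = list(
      model = saxs_model("core_shell", "hayter_penfold", scale = 0.39),
      form_params = core_shell_params(core_radius = 1.5, outer_radius = 2.45,
                                      rho_core = 0.291, rho_shell = 0.40,
                                      rho_solvent = 0.333),
      structure_params = hayter_penfold_params(hs_radius = 2.45,
                                               volume_fraction = 0.0117,
                                               z_eff = 10.8),
      concentration = 0.01,
      q = default_qgrid(150, 0.05, 5)),
    fractal_fresh = list(
      model = saxs_model("power_law"),
      form_params = power_law_params(amplitude = 1e-3, alpha = 2.6),
      structure_params = NULL,
      concentration = 0.01,
      q = default_qgrid(120, 0.02, 2)))
}

## --- CD ---------------------------------------------------------------------

gaussian_band <- function(wl, center, width) {
  exp(-(wl - center)^2 / (2 * width^2))
}

## per-residue reference band shapes; the helix shape is normalized so its
## 222 nm value is exactly -37400, the coil shape is constructed with a
## node at 222 nm so the helix-fraction arithmetic inverts exactly.
cd_helix_basis <- function(wl) {
  raw <- -(gaussian_band(wl, 222, 9.5) + 0.98 * gaussian_band(wl, 208, 7.0)) +
         2.1 * gaussian_band(wl, 190, 5.5)
  raw222 <- -(1 + 0.98 * gaussian_band(222, 208, 7.0)) +
            2.1 * gaussian_band(222, 190, 5.5)
  raw * (-37400 / raw222)
}

cd_coil_basis <- function(wl) {
  raw <- -1.05 * gaussian_band(wl, 198, 8.5) +
         0.15 * gaussian_band(wl, 222, 14)
  raw222 <- -1.05 * gaussian_band(222, 198, 8.5) + 0.15
  sc <- raw - raw222 * gaussian_band(wl, 222, 12)
  40000 * sc
}

#' Generate a synthetic CD spectrum
#'
#' Linear combination of fixed helix and coil reference band shapes
#' (helix: double minimum at 208/222 nm and a positive band at 190 nm;
#' coil: minimum near 198 nm), scaled so [cd_helicity()] recovers
#' `f_helix` exactly at zero noise, then converted to mdeg through the
#' inverse of the molar-ellipticity normalization.
#'
#' @param f_helix alpha-helix fraction in \[0, 1\].
#' @param n_residues residue count (default 31).
#' @param concentration molar concentration, mol/L.
#' @param pathlength path length, cm (default 0.001 = 0.01 mm cell).
#' @param noise_sd additive Gaussian noise in mdeg.
#' @param seed integer seed.
#' @param wavelength wavelength grid, nm.
#' @return a [cd_spectrum()].
#' @export
make_cd_spectrum <- function(f_helix, n_residues = 31L,
                             concentration = 2.4e-3, pathlength = 0.001,
                             noise_sd = 0, seed = 1L,
                             wavelength = seq(180, 280, by = 0.5)) {
  if (f_helix < 0 || f_helix > 1) stop("'f_helix' must be in [0, 1]",
                                       call. = FALSE)
  chain_corr <- 1 - 2.5 / n_residues
  theta_pr <- f_helix * chain_corr * cd_helix_basis(wavelength) +
              (1 - f_helix) * cd_coil_basis(wavelength)
  mdeg <- theta_pr * n_residues * 10 * concentration * pathlength
  if (noise_sd > 0) {
    mdeg <- with_local_seed(seed,
                            mdeg + stats::rnorm(length(mdeg), sd = noise_sd))
  }
  cd_spectrum(wavelength, mdeg, concentration = concentration,
              pathlength = pathlength, n_residues = n_residues)
}

## --- coordinates ------------------------------------------------------------

#' Generate a synthetic micelle (or dispersed) coordinate set
#'
#' Builds `p` coarse bead-chains.  In the `"micelle"` arrangement chains
#' point radially outward on a jittered Fibonacci direction set: tail beads
#' (united-atom CH2, 17 per chain like an octadecyl chain without the
#' terminal methyl) fill the hydrophobic core and head beads occupy the
#' shell.  In the `"dispersed"` arrangement (the trimer-style starting
#' state) chains are placed at random positions and orientations in a cubic
#' box, leaving their tails solvent-exposed.  A minimum distance between
#' beads of different chains is enforced by seeded rejection sampling.
#'
#' @param p association number (chains), >= 1.
#' @param core_radius hydrophobic core radius, nm.
#' @param shell_thickness head-group shell thickness, nm.
#' @param tail_beads,head_beads beads per chain in core and shell.
#' @param arrangement `"micelle"` or `"dispersed"`.
#' @param box dispersed-arrangement cubic box edge, nm.
#' @param min_dist minimum inter-chain bead distance, nm.
#' @param seed integer seed.
#' @param max_retry rejection-sampling retries per chain before a packing
#'   error is raised.
#' @return a [coordinate_set()] whose tail beads (elements `"CH2"`) lie
#'   within `core_radius` of the centre in the micelle arrangement.
#' @export
make_micelle_coordinates <- function(p, core_radius = 1.5,
                                     shell_thickness = 1.0,
                                     tail_beads = 17L, head_beads = 10L,
                                     arrangement = c("micelle", "dispersed"),
                                     box = 12, min_dist = 0.12, seed = 1L,
                                     max_retry = 200L) {
  arrangement <- match.arg(arrangement)
  if (p < 1) stop("'p' must be >= 1", call. = FALSE)
  n_bead <- tail_beads + head_beads
  with_local_seed(seed, {
    placed <- matrix(numeric(0), ncol = 3)
    all_pos <- vector("list", p)
    dirs <- fibonacci_sphere(max(p, 2L))[seq_len(p), , drop = FALSE]
    for (ch in seq_len(p)) {
      ok <- FALSE
      for (try in seq_len(max_retry)) {
        if (arrangement == "micelle") {
          d <- dirs[ch, ] + stats::rnorm(3, sd = 0.08)
          d <- d / sqrt(sum(d^2))
          ## volume-uniform bead radii (a wobbly, not straight, chain):
          ## gives a flat alkane-density core instead of a 1/r^2 pile-up
          r_tail <- core_radius *
            ((seq_len(tail_beads) - stats::runif(tail_beads)) /
             tail_beads)^(1 / 3)
          ro3 <- (core_radius + shell_thickness)^3
          r_head <- (core_radius^3 +
                     (seq_len(head_beads) - stats::runif(head_beads)) /
                     head_beads * (ro3 - core_radius^3))^(1 / 3)
          r <- c(r_tail, r_head)
          pos <- outer(r, d) + matrix(stats::rnorm(3 * n_bead, sd = 0.05),
                                      ncol = 3)
          ## keep tails inside the core by construction
          rr <- sqrt(rowSums(pos[seq_len(tail_beads), , drop = FALSE]^2))
          pos[seq_len(tail_beads), ] <-
            pos[seq_len(tail_beads), , drop = FALSE] *
            pmin(1, (core_radius - 1e-3) / rr)
        } else {
          origin <- stats::runif(3, 0, box)
          d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
          r <- (seq_len(n_bead) - 0.5) * 0.13
          pos <- sweep(outer(r, d), 2, origin, `+`) +
                 matrix(stats::rnorm(3 * n_bead, sd = 0.03), ncol = 3)
        }
        if (nrow(placed) == 0L) { ok <- TRUE; break }
        dmin <- min(vapply(seq_len(nrow(pos)), function(i) {
          min(rowSums(sweep(placed, 2, pos[i, ])^2))
        }, numeric(1)))
        if (dmin > min_dist^2) { ok <- TRUE; break }
      }
      if (!ok) stop("packing failed after ", max_retry,
                    " retries (chain ", ch, ")", call. = FALSE)
      all_pos[[ch]] <- pos
      placed <- rbind(placed, pos)
    }
    elements <- rep(c(rep("CH2", tail_beads), rep("O", head_beads)), p)
    coordinate_set(do.call(rbind, all_pos), elements)
  })
}

## --- titration --------------------------------------------------------------

#' Generate a synthetic probe-fluorescence titration
#'
#' Two-segment piecewise-linear response in log10 concentration with the
#' knot at the CMC: nearly flat below it (free probe), steeply increasing
#' above (probe partitioning into micelles), with multiplicative Gaussian
#' noise.
#'
#' @param cmc critical micelle concentration, wt %.
#' @param n_points number of log-spaced concentrations.
#' @param conc_range concentration span, wt % (must bracket `cmc`).
#' @param slope_below,slope_above response slopes per decade.
#' @param relative_sd multiplicative noise level.
#' @param seed integer seed.
#' @return data frame with `concentration` (wt %) and `response` (a.u.).
#' @export
make_titration <- function(cmc = 0.06, n_points = 14L,
                           conc_range = c(0.002, 1), slope_below = 0.05,
                           slope_above = 1.6, relative_sd = 0.03,
                           seed = 1L) {
  if (cmc <= conc_range[1] || cmc >= conc_range[2]) {
    stop("'cmc' must lie inside 'conc_range'", call. = FALSE)
  }
  conc <- 10^seq(log10(conc_range[1]), log10(conc_range[2]),
                 length.out = n_points)
  u <- log10(conc); k <- log10(cmc)
  resp <- 1 + slope_below * (u - u[1]) +
          (slope_above - slope_below) * pmax(u - k, 0)
  if (relative_sd > 0) {
    resp <- with_local_seed(seed,
                            resp * (1 + stats::rnorm(n_points,
                                                     sd = relative_sd)))
  }
  data.frame(concentration = conc, response = resp)
}
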