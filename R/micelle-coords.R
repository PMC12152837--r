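## Coordinate-set post-processing: radial electron-density profiles,
## solvent-accessible surface area (Shrake-Rupley) and aggregation
## propensity.  Positions in nm, densities reported in e/A^3.

## element -> (electrons, vdW radius nm); united-atom CHn pseudo-atoms carry
## the summed electron count and a slightly enlarged radius
element_table <- data.frame(
  element   = c("H", "C", "N", "O", "S", "P", "NA", "CL", "CH", "CH2", "CH3"),
  electrons = c(1, 6, 7, 8, 16, 15, 11, 17, 7, 8, 9),
  radius    = c(0.120, 0.170, 0.155, 0.152, 0.180, 0.180, 0.227, 0.175,
                0.190, 0.200, 0.210),
  stringsAsFactors = FALSE
)

#' Normalize atom/element names to table symbols
#'
#' Mixed-case element symbols and common united-atom names (`CH2`, `ch3`,
#' PDB-style atom names such as `CA`, `OD1`, `HB2`) are mapped to the
#' element symbols known to the lookup table; atom names are reduced to
#' their leading element letter when no pseudo-atom matches.
#'
#' @param names character vector of atom or element names.
#' @return normalized element symbols.
#' @export
elements_from_names <- function(names) {
  up <- toupper(trimws(names))
  out <- up
  known <- element_table$element
  unknown <- !(up %in% known)
  ## strip digits/primes then take leading one- or two-letter element
  core <- gsub("[^A-Z]", "", up[unknown])
  two <- substr(core, 1, 2)
  one <- substr(core, 1, 1)
  pick <- ifelse(two %in% c("NA", "CL") & nchar(core) == 2, two, one)
  out[unknown] <- pick
  bad <- !(out %in% known)
  if (any(bad)) {
    stop("unrecognized element(s): ", paste(unique(up[bad]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Construct a coordinate set
#'
#' Atoms with positions (nm), element symbols, per-atom electron counts and
#' van der Waals radii (nm).  Electrons and radii default to a neutral-atom
#' lookup by element.
#'
#' @param positions n x 3 numeric matrix of positions, nm.
#' @param elements character vector of element symbols (see
#'   [elements_from_names()]).
#' @param electrons optional per-atom electron counts.
#' @param radii optional per-atom van der Waals radii, nm.
#' @param frame_id optional frame identifier.
#' @return an object of class `"coordinate_set"`.
#' @export
coordinate_set <- function(positions, elements, electrons = NULL,
                           radii = NULL, frame_id = 1L) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L || any(!is.finite(positions))) {
    stop("'positions' must be a finite n x 3 matrix (nm)", call. = FALSE)
  }
  n <- nrow(positions)
  elements <- elements_from_names(elements)
  if (length(elements) != n) stop("'elements' must match positions",
                                  call. = FALSE)
  idx <- match(elements, element_table$element)
  if (is.null(electrons)) electrons <- element_table$electrons[idx]
  if (is.null(radii)) radii <- element_table$radius[idx]
  if (length(electrons) != n || any(electrons < 1)) {
    stop("'electrons' must be >= 1 per atom", call. = FALSE)
  }
  if (length(radii) != n || any(radii <= 0)) {
    stop("'radii' must be > 0 per atom", call. = FALSE)
  }
  structure(list(positions = unname(positions), elements = elements,
                 electrons = as.numeric(electrons), radii = as.numeric(radii),
                 frame_id = frame_id),
            class = "coordinate_set")
}

#' @export
print.coordinate_set <- function(x, ...) {
  cat(sprintf("Coordinate set: %d atoms, %.0f electrons (frame %s)\n",
              nrow(x$positions), sum(x$electrons), format(x$frame_id)))
  invisible(x)
}

#' Radial electron-density profile
#'
#' Electrons are summed in concentric spherical shells about the chosen
#' centre and divided by shell volume.  Each atom's electrons are assigned
#' wholly to the shell containing its centre, so the profile conserves
#' electrons exactly: sum(density x shell volume) equals the total electron
#' count.
#'
#' @param cs a [coordinate_set()] (at least 10 atoms).
#' @param center `"center_of_mass"` (electron-weighted, default) or
#'   `"geometric"`.
#' @param bin_width shell width, nm.
#' @return an object of class `"density_profile"`: a data frame with
#'   `bin_center` (nm) and `electron_density` (e/A^3), with attribute
#'   `bin_width`.
#' @export
radial_electron_density <- function(cs, center = c("center_of_mass",
                                                   "geometric"),
                                    bin_width = 0.05) {
  center <- match.arg(center)
  if (!inherits(cs, "coordinate_set")) stop("'cs' must be a coordinate_set",
                                            call. = FALSE)
  if (nrow(cs$positions) < 10L && nrow(cs$positions) > 1L) {
    warning("fewer than 10 atoms: profile will be noisy")
  }
  if (bin_width <= 0) stop("'bin_width' must be > 0", call. = FALSE)
  w <- if (center == "center_of_mass") cs$electrons / sum(cs$electrons)
       else rep(1 / nrow(cs$positions), nrow(cs$positions))
  ctr <- colSums(cs$positions * w)
  r <- sqrt(rowSums(sweep(cs$positions, 2, ctr)^2))
  nbins <- max(1L, ceiling(max(r) / bin_width + 1e-12))
  bin <- pmin(nbins, floor(r / bin_width) + 1L)
  esum <- vapply(seq_len(nbins),
                 function(b) sum(cs$electrons[bin == b]), numeric(1))
  edges <- (0:nbins) * bin_width
  vol_nm3 <- (4 / 3) * pi * diff(edges^3)
  dens <- esum / (vol_nm3 * 1000)            # nm^3 -> A^3
  structure(data.frame(bin_center = edges[-1] - bin_width / 2,
                       electron_density = dens),
            class = c("density_profile", "data.frame"),
            bin_width = bin_width, total_electrons = sum(cs$electrons))
}

## deterministic Fibonacci-lattice unit sphere points
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom's solvent-accessible sphere (radius r_i + probe) is sampled on
#' a deterministic Fibonacci point lattice; points falling inside any
#' neighbouring atom's accessible sphere are buried.  SASA per atom is the
#' exposed point fraction times the sphere area.
#'
#' @param cs a [coordinate_set()].
#' @param probe_radius solvent probe radius, nm (default 0.14, water).
#' @param n_points sampling points per atom (>= 32; default 960).
#' @return total area in nm^2, with per-atom areas in attribute
#'   `"per_atom"`.
#' @export
sasa <- function(cs, probe_radius = 0.14, n_points = 960L) {
  if (!inherits(cs, "coordinate_set")) stop("'cs' must be a coordinate_set",
                                            call. = FALSE)
  if (n_points < 32L) stop("'n_points' must be >= 32", call. = FALSE)
  pts <- fibonacci_sphere(n_points)
  pos <- cs$positions
  rad <- cs$radii + probe_radius
  n <- nrow(pos)
  areas <- numeric(n)
  ## neighbour prune: pair distance < r_i + r_j
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(pos, 2, pos[i, ])^2)
    nb <- which(d2 < (rad + rad[i])^2 & seq_len(n) != i)
    sp <- pts * rad[i]
    sp <- sweep(sp, 2, pos[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (sp[, 1] - pos[j, 1])^2 + (sp[, 2] - pos[j, 2])^2 +
             (sp[, 3] - pos[j, 3])^2
      exposed <- exposed & dj2 > rad[j]^2
      if (!any(exposed)) break
    }
    areas[i] <- 4 * pi * rad[i]^2 * mean(exposed)
  }
  structure(sum(areas), per_atom = areas)
}

#' Aggregation propensity from SASA compaction
#'
#' AP = SASA(initial) / SASA(final); values above 1 indicate that the final
#' configuration buries surface relative to the initial one, i.e. the
#' molecules pack together.
#'
#' @param initial,final [coordinate_set()] objects.
#' @param probe_radius solvent probe radius, nm.
#' @param n_points Shrake-Rupley sampling points per atom.
#' @return dimensionless AP.
#' @export
aggregation_propensity <- function(initial, final, probe_radius = 0.14,
                                   n_points = 960L) {
  s_f <- as.numeric(sasa(final, probe_radius, n_points))
  if (s_f <= 0) stop("final configuration has zero accessible area",
                     call. = FALSE)
  as.numeric(sasa(initial, probe_radius, n_points)) / s_f
}
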