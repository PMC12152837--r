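## File readers and writers: SAXS ASCII, CD CSV, PDB/GRO coordinates.
## Internal units everywhere: q in nm^-1, positions in nm.

parse_header_keys <- function(lines) {
  hdr <- grep("^\\s*#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^\\s*#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*[:=]\\s*(.+?)\\s*$",
                                hdr))
  out <- list()
  for (m in kv) if (length(m) == 3L) out[[m[2]]] <- m[3]
  out
}

#' Read a SAXS curve from whitespace-delimited ASCII
#'
#' Expects at least two numeric columns (q, I) and optionally a third
#' (sigma).  Comment lines start with `#`; header lines of the form
#' `# key: value` populate metadata (`concentration`, `label`).  Declared
#' Angstrom^-1 grids are converted to nm^-1 (x 10).
#'
#' @param path file path.
#' @param units units of the q column, `"nm-1"` (default) or `"A-1"`.
#' @return a [saxs_curve()].
#' @export
read_saxs_ascii <- function(path, units = c("nm-1", "A-1")) {
  units <- match.arg(units)
  lines <- readLines(path)
  meta <- parse_header_keys(lines)
  data_lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(data_lines)) stop("no data rows in ", path, call. = FALSE)
  fields <- strsplit(trimws(data_lines), "\\s+")
  ncol <- length(fields[[1]])
  if (ncol < 2L) stop("SAXS ASCII needs at least 2 columns (q, I)",
                      call. = FALSE)
  if (any(vapply(fields, length, 1L) != ncol)) {
    stop("inconsistent column count in ", path, call. = FALSE)
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = ncol, byrow = TRUE)
  if (any(!is.finite(m[, 1:2]))) stop("non-numeric data in ", path,
                                      call. = FALSE)
  q <- m[, 1]
  if (units == "A-1") q <- q * 10
  if (is.unsorted(q, strictly = TRUE)) {
    stop("q column must be strictly increasing", call. = FALSE)
  }
  conc <- if (!is.null(meta$concentration)) as.numeric(meta$concentration)
  saxs_curve(q, m[, 2], sigma = if (ncol >= 3L) m[, 3],
             concentration = conc,
             label = if (!is.null(meta$label)) meta$label else "")
}

#' @rdname read_saxs_ascii
#' @param curve a [saxs_curve()] to write.
#' @export
write_saxs_ascii <- function(curve, path) {
  hdr <- c("# q(nm^-1) I(cm^-1)" ,
           if (!is.null(curve$sigma)) "# third column: sigma(cm^-1)")
  meta <- character()
  if (!is.null(attr(curve, "concentration"))) {
    meta <- c(meta, sprintf("# concentration: %.10g",
                            attr(curve, "concentration")))
  }
  if (nzchar(attr(curve, "label"))) {
    meta <- c(meta, paste("# label:", attr(curve, "label")))
  }
  cols <- cbind(curve$q, curve$intensity,
                if (!is.null(curve$sigma)) curve$sigma)
  body <- apply(cols, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = " "))
  writeLines(c(hdr, meta, body), path)
  invisible(path)
}

#' Read a CD spectrum from a two-column CSV
#'
#' Columns: wavelength (nm), ellipticity (mdeg).  A `#`-prefixed header block
#' supplies `concentration` (mol/L), `pathlength` (cm) and `n_residues`.
#'
#' @param path file path.
#' @return a [cd_spectrum()].
#' @export
read_cd_csv <- function(path) {
  lines <- readLines(path)
  meta <- parse_header_keys(lines)
  data_lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  ## tolerate a non-numeric column-name row
  first <- strsplit(data_lines[1], ",")[[1]]
  if (any(is.na(suppressWarnings(as.numeric(first))))) {
    data_lines <- data_lines[-1]
  }
  m <- do.call(rbind, lapply(strsplit(data_lines, ","),
                             function(x) as.numeric(x[1:2])))
  cd_spectrum(wavelength = m[, 1], ellipticity = m[, 2],
              concentration = as.numeric(meta$concentration),
              pathlength = as.numeric(meta$pathlength),
              n_residues = as.integer(meta$n_residues))
}

#' @rdname read_cd_csv
#' @param spectrum a [cd_spectrum()] to write.
#' @export
write_cd_csv <- function(spectrum, path) {
  s <- spectrum
  writeLines(c(sprintf("# concentration: %.10g", s$concentration),
               sprintf("# pathlength: %.10g", s$pathlength),
               sprintf("# n_residues: %d", s$n_residues),
               "wavelength_nm,ellipticity_mdeg",
               sprintf("%.17g,%.17g", s$wavelength, s$ellipticity)), path)
  invisible(path)
}

## --- coordinates ------------------------------------------------------------

#' Read atomic coordinates from PDB or GRO
#'
#' PDB files are parsed with \pkg{bio3d} (positions converted from Angstrom
#' to nm); GRO files are parsed directly (positions already in nm, any
#' velocity columns ignored).  Elements are inferred from atom names by PDB
#' conventions and mapped to electron counts and van der Waals radii;
#' united-atom CH/CH2/CH3 pseudo-atom names are recognised and assigned the
#' summed electron count.
#'
#' @param path file path ending in `.pdb` or `.gro`.
#' @return a [coordinate_set()].
#' @export
read_coordinates <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdb") {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    pos <- cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z) / 10
    ## prefer the atom name when it denotes a united-atom pseudo-particle
    ## (CHn); otherwise use the element column, falling back to the name
    nm <- trimws(pdb$atom$elesy)
    aname <- toupper(trimws(pdb$atom$elety))
    pseudo <- aname %in% c("CH", "CH2", "CH3")
    nm[pseudo] <- aname[pseudo]
    nm[!nzchar(nm)] <- aname[!nzchar(nm)]
    coordinate_set(pos, elements_from_names(nm))
  } else if (ext == "gro") {
    lines <- readLines(path)
    n_atoms <- as.integer(trimws(lines[2]))
    rec <- lines[3:(2 + n_atoms)]
    name <- trimws(substr(rec, 11, 15))
    xx <- as.numeric(substr(rec, 21, 28))
    yy <- as.numeric(substr(rec, 29, 36))
    zz <- as.numeric(substr(rec, 37, 44))
    if (any(!is.finite(c(xx, yy, zz)))) {
      bad <- which(!is.finite(xx) | !is.finite(yy) | !is.finite(zz))
      stop("unparseable GRO atom records at lines ",
           paste(bad + 2L, collapse = ", "), call. = FALSE)
    }
    coordinate_set(cbind(xx, yy, zz), elements_from_names(name))
  } else {
    stop("unsupported coordinate format: ", ext, call. = FALSE)
  }
}

#' @rdname read_coordinates
#' @param cs a [coordinate_set()] to write (PDB, nm -> Angstrom).
#' @export
write_coordinates_pdb <- function(cs, path) {
  pos <- cs$positions * 10
  ## united-atom pseudo-particles keep their name in the atom-name column
  ## but write the parent element in the element column
  elem <- ifelse(grepl("^CH", cs$elements), "C", substr(cs$elements, 1, 2))
  lines <- sprintf(
    "ATOM  %5d %-4s UNK A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(pos)), substr(cs$elements, 1, 4), 1L,
    pos[, 1], pos[, 2], pos[, 3], elem)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
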