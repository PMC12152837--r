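## Transepithelial electrical resistance (TEER) arithmetic.

#' TEER from raw resistance readings
#'
#' TEER = (R_total - R_blank) x membrane area.  Readings below the
#' monolayer-quality cutoff (default 120 Ohm cm^2) are flagged as excluded,
#' not rejected; negative tissue resistances are flagged too.
#'
#' @param r_total total resistance with the cell monolayer, Ohm.
#' @param r_blank blank (no-cell) resistance, Ohm.
#' @param membrane_area transwell membrane area, cm^2 (default 1.12).
#' @param cutoff quality cutoff, Ohm cm^2; `NA` disables flagging.
#' @return numeric TEER values, Ohm cm^2, with logical attributes
#'   `"excluded"` (below cutoff) and `"negative"` (r_total < r_blank).
#' @export
teer <- function(r_total, r_blank, membrane_area = 1.12, cutoff = 120) {
  if (any(membrane_area <= 0)) stop("'membrane_area' must be > 0",
                                    call. = FALSE)
  val <- (r_total - r_blank) * membrane_area
  structure(val,
            excluded = if (!is.na(cutoff)) val < cutoff else rep(FALSE,
                                                                 length(val)),
            negative = r_total < r_blank)
}

#' TEER as percentage of a control series
#'
#' 100 x TEER / TEER_control at matched timepoints.
#'
#' @param series data frame with columns `timepoint` and `teer`.
#' @param control_series data frame with the same columns covering every
#'   timepoint of `series`.
#' @return data frame with `timepoint` and `percent_of_control`.
#' @export
teer_percent_of_control <- function(series, control_series) {
  i <- match(series$timepoint, control_series$timepoint)
  if (any(is.na(i))) {
    stop("control series is missing timepoint(s): ",
         paste(series$timepoint[is.na(i)], collapse = ", "), call. = FALSE)
  }
  data.frame(timepoint = series$timepoint,
             percent_of_control = 100 * series$teer / control_series$teer[i])
}
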