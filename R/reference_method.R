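#' HPLC calibration line
#'
#' A straight-line response model `area = slope * concentration +
#' intercept`, with the concentration range over which it was validated.
#' The defaults are the validated chlorpheniramine maleate assay line
#' (`y = 14603 x - 2363` over 10-30 ug/mL).
#'
#' @param slope Peak area per (ug/mL); must be positive.
#' @param intercept Peak area at zero concentration.
#' @param valid_range Length-2 numeric, the validated concentration range
#'   in ug/mL.
#' @return A `calibration_line` object.
#' @export
calibration_line <- function(slope = 14603, intercept = -2363,
                             valid_range = c(10, 30)) {
  if (!is.finite(slope) || slope <= 0) {
    stop_chemocal("calibration slope must be positive", "parameter_error")
  }
  if (length(valid_range) != 2 || valid_range[1] >= valid_range[2]) {
    stop_chemocal("valid_range must be (lo, hi) with lo < hi", "parameter_error")
  }
  structure(list(slope = slope, intercept = intercept,
                 valid_range = as.numeric(valid_range)),
            class = "calibration_line")
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf("<calibration_line> area = %g * conc %+g  (validated %g-%g ug/mL)\n",
              x$slope, x$intercept, x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Back-calculate analyte content from peak areas
#'
#' Inverts the calibration line to a concentration, then undoes the sample
#' dilution: `content_mg = conc_ug_mL * dilution_factor * volume_mL / 1000`.
#' Concentrations outside the line's validated range are flagged (not
#' rejected): real dosage series can legitimately fall outside the range a
#' single dilution scheme was validated for, and the caller decides what to
#' do about it. Negative implied concentrations are an error.
#'
#' @param peak_area Numeric vector of chromatographic peak areas.
#' @param line A [calibration_line()].
#' @param dilution_factor Overall dilution between the volumetric make-up
#'   and the injected solution (e.g. 10 for a 1 mL to 10 mL transfer).
#' @param volume_mL Volume the dosage unit was dissolved into (mL).
#' @return A tibble: `peak_area`, `conc_ug_mL`, `content_mg`, `in_range`.
#' @examples
#' backcalc_content(143667, calibration_line(), dilution_factor = 10,
#'                  volume_mL = 25)
#' @export
backcalc_content <- function(peak_area, line = calibration_line(),
                             dilution_factor = 10, volume_mL = 25) {
  conc <- (peak_area - line$intercept) / line$slope
  if (any(conc < 0)) {
    stop_chemocal("peak area implies a negative concentration", "quantitation_error")
  }
  tibble(
    peak_area = peak_area,
    conc_ug_mL = conc,
    content_mg = conc * dilution_factor * volume_mL / 1000,
    in_range = conc >= line$valid_range[1] & conc <= line$valid_range[2]
  )
}

#' Column length-to-particle-size ratio (L/dp)
#'
#' The dimensionless ratio USP general chapter <621> uses to judge whether
#' an isocratic method may be transferred between columns:
#' `length_mm * 1000 / particle_size_um`.
#'
#' @param length_mm Column length in mm (> 0).
#' @param particle_size_um Packing particle diameter in um (> 0).
#' @return The L/dp ratio.
#' @examples
#' ldp_ratio(150, 5)  # 30000
#' @export
ldp_ratio <- function(length_mm, particle_size_um) {
  if (any(length_mm <= 0) || any(particle_size_um <= 0)) {
    stop_chemocal("column geometry must be positive", "parameter_error")
  }
  length_mm * 1000 / particle_size_um
}

#' Allowed L/dp range for column substitution
#'
#' USP permits changing column length and/or particle size for isocratic
#' separations when the new L/dp stays within -25 to +50 percent of the
#' prescribed column's ratio, i.e. `(0.75 * R, 1.50 * R)`.
#'
#' @param length_mm,particle_size_um Geometry of the prescribed (reference)
#'   column.
#' @return Named numeric of length 2, `lo` and `hi`.
#' @examples
#' ldp_allowed_range(250, 5)  # 37500 75000
#' @export
ldp_allowed_range <- function(length_mm, particle_size_um) {
  r <- ldp_ratio(length_mm, particle_size_um)
  c(lo = 0.75 * r, hi = 1.50 * r)
}

#' Check a test column against a reference column's L/dp window
#'
#' @param test_length_mm,test_particle_um Geometry of the candidate column.
#' @param ref_length_mm,ref_particle_um Geometry of the prescribed column.
#' @return A one-row tibble: `test_ratio`, `lo`, `hi`, `within` (logical),
#'   `position` (`"below"`, `"within"`, `"above"`).
#' @examples
#' ldp_check(150, 5, 250, 5)  # 30000 is below the 37500-75000 window
#' @export
ldp_check <- function(test_length_mm, test_particle_um,
                      ref_length_mm, ref_particle_um) {
  r <- ldp_ratio(test_length_mm, test_particle_um)
  rng <- ldp_allowed_range(ref_length_mm, ref_particle_um)
  tibble(
    test_ratio = r, lo = rng[["lo"]], hi = rng[["hi"]],
    within = r >= rng[["lo"]] & r <= rng[["hi"]],
    position = if (r < rng[["lo"]]) "below" else if (r > rng[["hi"]]) "above" else "within"
  )
}
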