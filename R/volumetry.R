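# Radius -> volume models, and the equivalent circular radius used to turn
# CT cross-sectional areas into reference radii. Volumes are returned in mL
# (1 mL = 1000 mm^3).

#' Wyatt volume model
#'
#' Ellipsoid-corrected volume of a ventricle of centre radius `R` and height
#' `LV_h`: `LVV = (5/6) * pi * R^2 * LV_h`. The 5/6 factor discounts the
#' cylinder towards an ellipsoid-like shape tapering at apex and base.
#'
#' @param R_mm Centre radius (mm); vectorised.
#' @param LV_h_mm Ventricle height (mm).
#' @return Volume in mL.
#' @examples
#' wyatt_volume(R_mm = 10, LV_h_mm = 100) # ~26.18 mL
#' @export
wyatt_volume <- function(R_mm, LV_h_mm) {
  .check_nonneg(R_mm, "R_mm")
  .check_pos(LV_h_mm, "LV_h_mm")
  (5 / 6) * pi * R_mm^2 * LV_h_mm / 1000
}

#' Cylindrical volume model
#'
#' Plain cylinder `V = pi * R^2 * L`, the volume model of the classical
#' conductance method: the sensed segment is treated as a cylinder of the
#' estimated radius.
#'
#' @param R_mm Radius (mm); vectorised.
#' @param L_mm Segment length / ventricle height (mm).
#' @return Volume in mL.
#' @examples
#' cylinder_volume(R_mm = 10, L_mm = 20) # ~6.283 mL
#' @export
cylinder_volume <- function(R_mm, L_mm) {
  .check_nonneg(R_mm, "R_mm")
  .check_pos(L_mm, "L_mm")
  pi * R_mm^2 * L_mm / 1000
}

#' Equivalent circular radius of a cross-sectional area
#'
#' Radius of the circle with the same area, `sqrt(A / pi)`; the reference
#' radius assigned to a non-circular cavity cross-section measured (e.g. by
#' CT) at the level of the centre electrode pair.
#'
#' @param A_mm2 Cross-sectional area (mm^2); vectorised, must be `>= 0`.
#' @return Radius in mm.
#' @examples
#' equivalent_radius_from_area(1248.84) # 19.94 mm
#' @export
equivalent_radius_from_area <- function(A_mm2) {
  .check_nonneg(A_mm2, "A_mm2")
  sqrt(A_mm2 / pi)
}

.check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0)) {
    stop(sprintf("%s must be numeric and >= 0", name), call. = FALSE)
  }
  invisible(x)
}

.check_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("%s must be a single value > 0", name), call. = FALSE)
  }
  invisible(x)
}
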