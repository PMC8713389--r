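#' Tetrapolar electrode geometry
#'
#' Describes the catheter geometry of a tetrapolar intracardiac conductance
#' measurement: two outer injection electrodes (modelled as small charged
#' spheres of radius `r0_mm`) separated by `d_mm`, and two inner measurement
#' electrodes separated by `L_mm`, all on a common axis centred at the origin.
#'
#' Geometric constraints enforced: `r0_mm > 0`, `0 < L_mm < d_mm` (the
#' injection pair is the outer pair, and the Wei voltage term requires
#' `d^2 - L^2 > 0`), and `r0_mm < L_mm / 2` so the injection spheres do not
#' overlap the measurement electrodes.
#'
#' Lengths are accepted in millimetres at every API boundary of this package
#' and converted to metres internally, so that conductances come out in
#' siemens when conductivities are supplied in S/m.
#'
#' @param r0_mm Radius of the injection-electrode spheres (mm).
#' @param d_mm Spacing of the outer (injection) electrode pair (mm).
#' @param L_mm Spacing of the inner (measurement) electrode pair (mm).
#'
#' @return An object of class `lv_electrode_config`.
#' @examples
#' cfg <- electrode_config(r0_mm = 1, d_mm = 40, L_mm = 20)
#' cfg
#' @export
electrode_config <- function(r0_mm = 1, d_mm = 40, L_mm = 20) {
  cfg <- new_electrode_config(r0_mm, d_mm, L_mm)
  if (cfg$L_mm >= cfg$d_mm) {
    stop("electrode_config: requires L_mm < d_mm (injection pair is the outer pair)",
         call. = FALSE)
  }
  cfg
}

# Internal constructor without the L < d ordering check. Used to express the
# d <-> L electrode-role interchange when checking reciprocity; the lead model
# must be invariant under it.
new_electrode_config <- function(r0_mm, d_mm, L_mm) {
  stopifnot(is.numeric(r0_mm), is.numeric(d_mm), is.numeric(L_mm),
            length(r0_mm) == 1L, length(d_mm) == 1L, length(L_mm) == 1L)
  if (!is.finite(r0_mm) || !is.finite(d_mm) || !is.finite(L_mm)) {
    stop("electrode_config: geometry must be finite", call. = FALSE)
  }
  if (r0_mm <= 0) stop("electrode_config: r0_mm must be > 0", call. = FALSE)
  if (d_mm <= 0 || L_mm <= 0) {
    stop("electrode_config: spacings must be > 0", call. = FALSE)
  }
  if (d_mm == L_mm) {
    stop("electrode_config: d_mm and L_mm must differ", call. = FALSE)
  }
  if (r0_mm >= min(L_mm, d_mm) / 2) {
    stop("electrode_config: requires r0_mm < L_mm / 2 (spheres must not reach the measurement electrodes)",
         call. = FALSE)
  }
  structure(list(r0_mm = r0_mm, d_mm = d_mm, L_mm = L_mm),
            class = "lv_electrode_config")
}

# Electrode-role interchange d <-> L (reciprocity check helper).
swap_injection_measurement <- function(cfg) {
  new_electrode_config(cfg$r0_mm, d_mm = cfg$L_mm, L_mm = cfg$d_mm)
}

#' @export
print.lv_electrode_config <- function(x, ...) {
  cat("<tetrapolar electrode configuration>\n")
  cat(sprintf("  injection sphere radius r0: %.3g mm\n", x$r0_mm))
  cat(sprintf("  injection spacing d:        %.3g mm\n", x$d_mm))
  cat(sprintf("  measurement spacing L:      %.3g mm\n", x$L_mm))
  invisible(x)
}

#' Conductive compartments surrounding the catheter
#'
#' The medium is modelled as three concentric compartments around the
#' electrode axis: the blood (or saline) pool out to the cavity radius `R`,
#' a muscle/wall shell of thickness `wall_thickness_mm`, and background
#' tissue from the outer wall surface out to
#' `background_outer_radius_mm` (which may be `Inf`; the conductance
#' integrals converge, so an unbounded background is well defined).
#'
#' @param sigma_blood_S_per_m Conductivity of the blood / saline pool (S/m).
#' @param sigma_muscle_S_per_m Conductivity of the muscle (wall) shell (S/m).
#' @param sigma_background_S_per_m Conductivity of the background (S/m).
#' @param wall_thickness_mm Radial thickness of the wall shell (mm).
#' @param background_outer_radius_mm Outer radial extent of the background
#'   compartment (mm), measured from the axis; `Inf` for an unbounded
#'   background.
#'
#' @return An object of class `lv_tissue_model`.
#' @examples
#' # saline in a glass container: insulating wall and background
#' tissue_model(sigma_blood_S_per_m = 1.68)
#' # ventricle phantom with conductive wall and saline-tank background
#' tissue_model(0.7, 0.3, 0.2, wall_thickness_mm = 10,
#'              background_outer_radius_mm = 200)
#' @export
tissue_model <- function(sigma_blood_S_per_m,
                         sigma_muscle_S_per_m = 0,
                         sigma_background_S_per_m = 0,
                         wall_thickness_mm = 10,
                         background_outer_radius_mm = Inf) {
  sig <- c(sigma_blood_S_per_m, sigma_muscle_S_per_m, sigma_background_S_per_m)
  stopifnot(is.numeric(sig), length(sig) == 3L, all(!is.na(sig)))
  if (any(sig < 0)) stop("tissue_model: conductivities must be >= 0", call. = FALSE)
  if (!is.numeric(wall_thickness_mm) || wall_thickness_mm < 0) {
    stop("tissue_model: wall_thickness_mm must be >= 0", call. = FALSE)
  }
  if (!is.numeric(background_outer_radius_mm) || background_outer_radius_mm <= 0) {
    stop("tissue_model: background_outer_radius_mm must be > 0 (may be Inf)",
         call. = FALSE)
  }
  structure(
    list(sigma_blood_S_per_m = sigma_blood_S_per_m,
         sigma_muscle_S_per_m = sigma_muscle_S_per_m,
         sigma_background_S_per_m = sigma_background_S_per_m,
         wall_thickness_mm = wall_thickness_mm,
         background_outer_radius_mm = background_outer_radius_mm),
    class = "lv_tissue_model"
  )
}

#' @export
print.lv_tissue_model <- function(x, ...) {
  cat("<tissue compartment model>\n")
  cat(sprintf("  sigma blood:      %.4g S/m\n", x$sigma_blood_S_per_m))
  cat(sprintf("  sigma muscle:     %.4g S/m (wall thickness %.3g mm)\n",
              x$sigma_muscle_S_per_m, x$wall_thickness_mm))
  cat(sprintf("  sigma background: %.4g S/m (outer radius %s mm)\n",
              x$sigma_background_S_per_m,
              ifelse(is.finite(x$background_outer_radius_mm),
                     format(x$background_outer_radius_mm), "Inf")))
  invisible(x)
}

# mm -> m at the API boundary; all internal field/conductance math is SI.
.mm <- function(x) x * 1e-3

.assert_cfg <- function(cfg) {
  if (!inherits(cfg, "lv_electrode_config")) {
    stop("expected an `lv_electrode_config` (see electrode_config())", call. = FALSE)
  }
  invisible(cfg)
}

.assert_tissue <- function(tissue) {
  if (!inherits(tissue, "lv_tissue_model")) {
    stop("expected an `lv_tissue_model` (see tissue_model())", call. = FALSE)
  }
  invisible(tissue)
}
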