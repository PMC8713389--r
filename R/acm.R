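# Closed-form conductance models. All closed forms below are derived from
# the field definitions (two-point-charge dipole, sphere + charged plate)
# by carrying out the current integral over the z = 0 annulus and the
# voltage integral along the axis, and are certified against the quadrature
# oracle (numeric_current / numeric_voltage) in the test suite. Lengths in
# metres internally; conductances are reported as positive magnitudes.

# 1 / sqrt(s^2 + 4 x^2); the recurring axial-distance kernel. x may be Inf.
.axk <- function(s, x) ifelse(is.finite(x), 1 / sqrt(s^2 + 4 * x^2), 0)

# |current| of a dipole with charge separation s integrated over the annulus
# [a, b] of the z = 0 plane, per unit source strength k = V0 * r0:
#   |I| = 4 pi sigma k s (1/sqrt(s^2+4a^2) - 1/sqrt(s^2+4b^2))
.dipole_current_mag <- function(s, sigma, a, b, k = 1) {
  4 * pi * sigma * k * s * (.axk(s, a) - .axk(s, b))
}

# |voltage| across the electrode pair at +-m/2 due to a dipole at +-s/2,
# per unit k. Symmetric in (s, m): V = 4 k (1/|s-m| - 1/(s+m)).
.pair_voltage_mag <- function(s, m, k = 1) {
  4 * k * (1 / abs(s - m) - 1 / (s + m))
}

#' Classical two-point-charge (Wei) conductance of the blood pool
#'
#' Conductance of a homogeneous pool of radius `R_mm` seen by a tetrapolar
#' catheter, modelling the injection electrodes as two opposite point
#' charges. Obtained as the ratio of the dipole current through the
#' `[r0, R]` annulus of the mid-plane to the on-axis voltage across the
#' measurement pair:
#'
#' `G = pi * sigma * d * (d^2 - L^2) / (2 L) * (1/sqrt(d^2 + 4 r0^2) - 1/sqrt(d^2 + 4 R^2))`
#'
#' Strictly increasing in `R`, zero at `R = r0`, and bounded above by its
#' `R -> Inf` limit.
#'
#' @param R_mm Cavity radius (mm); vectorised. Must be `>= cfg$r0_mm`
#'   (`Inf` gives the saturation limit).
#' @param cfg An [electrode_config()].
#' @param sigma Conductivity of the pool (S/m).
#'
#' @return Conductance in siemens.
#' @examples
#' wei_conductance(20, electrode_config(), sigma = 0.7)
#' @export
wei_conductance <- function(R_mm, cfg, sigma) {
  .assert_cfg(cfg)
  if (any(is.na(R_mm)) || any(R_mm < cfg$r0_mm)) {
    stop("wei_conductance: requires R_mm >= r0_mm (cavity cannot be smaller than the electrode)",
         call. = FALSE)
  }
  annulus_conductance(cfg$r0_mm, R_mm, cfg, sigma)
}

#' Wei-style conductance of a radial annulus
#'
#' The classical model extended to an arbitrary annulus `[R_in, R_out]` of
#' the mid-plane by moving the limits of the current integral; used for the
#' muscle shell (`[R, R + b]`) and the background (`[R + b, R_ba]`)
#' compartment terms. Telescopes exactly:
#' `annulus(a, b) + annulus(b, c) = annulus(a, c)`.
#'
#' @param R_in_mm,R_out_mm Annulus bounds (mm), `cfg$r0_mm <= R_in_mm <=
#'   R_out_mm`; vectorised; `R_out_mm` may be `Inf`.
#' @inheritParams wei_conductance
#' @return Conductance in siemens.
#' @export
annulus_conductance <- function(R_in_mm, R_out_mm, cfg, sigma) {
  .assert_cfg(cfg)
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  n <- max(length(R_in_mm), length(R_out_mm))
  R_in_mm <- rep_len(R_in_mm, n); R_out_mm <- rep_len(R_out_mm, n)
  if (any(is.na(R_in_mm)) || any(is.na(R_out_mm))) {
    stop("annulus_conductance: bounds must not be NA", call. = FALSE)
  }
  if (any(R_in_mm < cfg$r0_mm)) {
    stop("annulus_conductance: inner bound below the electrode radius r0",
         call. = FALSE)
  }
  if (any(R_out_mm < R_in_mm)) {
    stop("annulus_conductance: requires R_in_mm <= R_out_mm", call. = FALSE)
  }
  d <- .mm(cfg$d_mm); L <- .mm(cfg$L_mm)
  a <- .mm(R_in_mm); b <- .mm(R_out_mm)
  # |I| / |V| with |I| = 4 pi sigma k d (kern(a) - kern(b)),
  # |V| = 8 k L / (d^2 - L^2)
  pi * sigma * d * abs(d^2 - L^2) / (2 * L) * (.axk(d, a) - .axk(d, b))
}

#' Plate-model conductance of the blood pool
#'
#' Blood-pool conductance of the sphere-plus-charged-plate source
#' configuration, which emulates the compression of the electric field into
#' the conductive cavity at the blood-muscle boundary. Current over the
#' `[r0, R]` mid-plane annulus and voltage as twice the on-axis integral
#' over `[0, L/2]` (mirror symmetry about the plate plane):
#'
#' * `|I| = 2 pi sigma k [ d (1/sqrt(d^2+4r0^2) - 1/sqrt(d^2+4R^2)) + 1 - r0^2/R^2 ]`
#' * `|V| = 2 k [ 2 L / (d (d - L)) + (2/R^2) (L/2 + R - sqrt(L^2/4 + R^2)) ]`
#'
#' The uniform charge distribution on the plate stops being a good surrogate
#' once the cavity radius approaches the measurement spacing; radii with
#' `R >= L` are computed but flagged with a validity warning.
#'
#' @inheritParams wei_conductance
#' @param R_mm Cavity (plate) radius (mm); vectorised; must be `> cfg$r0_mm`.
#' @param warn Emit the `R >= L` validity warning (default `TRUE`).
#' @return Conductance in siemens.
#' @examples
#' plate_blood_conductance(15, electrode_config(), sigma = 0.7)
#' @export
plate_blood_conductance <- function(R_mm, cfg, sigma, warn = TRUE) {
  .assert_cfg(cfg)
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  if (any(is.na(R_mm)) || any(R_mm <= cfg$r0_mm)) {
    stop("plate_blood_conductance: requires R_mm > r0_mm", call. = FALSE)
  }
  if (warn && any(R_mm >= cfg$L_mm)) {
    warning("plate_blood_conductance: R >= L lies outside the plate model's validity range (uniform plate charge); values flagged, not suppressed",
            call. = FALSE)
  }
  r0 <- .mm(cfg$r0_mm); d <- .mm(cfg$d_mm); L <- .mm(cfg$L_mm)
  R <- .mm(R_mm)
  I_mag <- 2 * pi * sigma * (d * (.axk(d, r0) - .axk(d, R)) + 1 - r0^2 / R^2)
  V_mag <- 2 * (2 * L / (d * (d - L)) +
                  (2 / R^2) * (L / 2 + R - sqrt(L^2 / 4 + R^2)))
  I_mag / V_mag
}

#' Lead-model injection and measurement currents
#'
#' The two dipole currents of the lead (reciprocity) construction: the
#' current of the injection field (charge separation `d`) and of the
#' measurement field (separation `L`), each integrated over the same annulus
#' `[rho_in, rho_out]` of the mid-plane. Signed with the convention that the
#' integrated `E_z` of a dipole is negative over its mid-plane.
#'
#' @inheritParams wei_conductance
#' @param rho_in_mm,rho_out_mm Annulus bounds (mm), `rho_in_mm <=
#'   rho_out_mm`; `rho_out_mm` may be `Inf`.
#' @param V0 Drive potential (V).
#' @return A tibble with columns `I_d_A` and `I_L_A` (amperes).
#' @examples
#' lead_currents(electrode_config(), sigma = 0.7, rho_in_mm = 1, rho_out_mm = 20)
#' @export
lead_currents <- function(cfg, sigma, rho_in_mm, rho_out_mm, V0 = 1) {
  .assert_cfg(cfg)
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  n <- max(length(rho_in_mm), length(rho_out_mm))
  rho_in_mm <- rep_len(rho_in_mm, n); rho_out_mm <- rep_len(rho_out_mm, n)
  if (any(is.na(rho_in_mm)) || any(is.na(rho_out_mm)) ||
      any(rho_out_mm < rho_in_mm)) {
    stop("lead_currents: requires rho_in_mm <= rho_out_mm", call. = FALSE)
  }
  k <- V0 * .mm(cfg$r0_mm)
  a <- .mm(rho_in_mm); b <- .mm(rho_out_mm)
  tibble::tibble(
    I_d_A = -.dipole_current_mag(.mm(cfg$d_mm), sigma, a, b, k),
    I_L_A = -.dipole_current_mag(.mm(cfg$L_mm), sigma, a, b, k)
  )
}

#' Reciprocal voltage of the tetrapolar pair
#'
#' On-axis voltage across one electrode pair due to a dipole on the other
#' pair. Identical whichever pair injects (`V_d = V_L`, the reciprocity
#' relation), and therefore written in the manifestly symmetric form
#' `V_all = 4 k (1/|d - L| - 1/(d + L))` with `k = V0 * r0`.
#'
#' @inheritParams lead_currents
#' @return Voltage magnitude in volts.
#' @export
v_all <- function(cfg, V0 = 1) {
  .assert_cfg(cfg)
  k <- V0 * .mm(cfg$r0_mm)
  .pair_voltage_mag(.mm(cfg$d_mm), .mm(cfg$L_mm), k)
}

#' Lead-model conductance of one compartment
#'
#' Combines the injection and measurement currents into the reciprocal
#' current `I_lead = sqrt(I_L * I_d)` (the balanced, unit-less weighting of
#' the two fields demanded by reciprocity) and divides by the common voltage
#' `V_all`: `G = sqrt(|I_d * I_L|) / |V_all|`. Invariant under interchanging
#' the injection and measurement roles.
#'
#' @param I_d_A,I_L_A Currents of the `d`- and `L`-spacing dipoles (A);
#'   must carry the same sign (opposite signs indicate a non-physical
#'   configuration and raise an error).
#' @param V_all_V Reciprocal pair voltage (V), see [v_all()].
#' @return Conductance in siemens (non-negative).
#' @export
lead_compartment_conductance <- function(I_d_A, I_L_A, V_all_V) {
  n <- max(length(I_d_A), length(I_L_A))
  I_d_A <- rep_len(I_d_A, n); I_L_A <- rep_len(I_L_A, n)
  if (any(I_d_A * I_L_A < 0)) {
    stop("lead_compartment_conductance: I_d and I_L have opposite signs (non-physical configuration)",
         call. = FALSE)
  }
  stopifnot(is.numeric(V_all_V), length(V_all_V) == 1L, V_all_V != 0)
  sqrt(abs(I_d_A * I_L_A)) / abs(V_all_V)
}

# Compartment bounds (mm) for a cavity radius R: blood [r0, R],
# muscle [R, R+b], background [R+b, R_ba].
.compartment_bounds <- function(R_mm, cfg, tissue) {
  b <- tissue$wall_thickness_mm
  list(blood = cbind(cfg$r0_mm, R_mm),
       muscle = cbind(R_mm, R_mm + b),
       background = cbind(R_mm + b,
                          pmax(R_mm + b, tissue$background_outer_radius_mm)))
}

#' Total conductance of an analytical calculation method
#'
#' Evaluates the forward model `G(R)` of one of the three analytical
#' calculation methods (ACMs), split into blood, muscle and background
#' compartment conductances whose sum is the total:
#'
#' * `"wei"` - classical two-point-charge model; compartment terms are
#'   Wei-style annulus conductances with the compartment conductivity.
#' * `"plate"` - blood term from the sphere-plus-plate model
#'   ([plate_blood_conductance()]); muscle and background terms are
#'   Wei-style annulus extensions.
#' * `"lead"` - every compartment built from the reciprocity construction
#'   ([lead_currents()] on the compartment's annulus with its conductivity,
#'   through [lead_compartment_conductance()] with the common [v_all()]).
#'
#' @param R_mm Cavity radius (mm); vectorised.
#' @param cfg An [electrode_config()].
#' @param tissue An [tissue_model()].
#' @param acm One of `"wei"`, `"plate"`, `"lead"`.
#'
#' @return A tibble with one row per radius: `acm`, `R_mm`, `G_blood_S`,
#'   `G_muscle_S`, `G_background_S`, `G_total_S`, and `in_validity`
#'   (`FALSE` for plate radii at or beyond the measurement spacing `L`).
#' @examples
#' cfg <- electrode_config()
#' tis <- tissue_model(0.7, 0.3, 0.2, background_outer_radius_mm = 200)
#' acm_conductance(c(10, 15, 20), cfg, tis, acm = "lead")
#' @export
acm_conductance <- function(R_mm, cfg, tissue, acm = c("wei", "plate", "lead")) {
  .assert_cfg(cfg); .assert_tissue(tissue)
  acm <- match.arg(acm)
  if (any(is.na(R_mm)) || any(R_mm < cfg$r0_mm)) {
    stop("acm_conductance: requires R_mm >= r0_mm", call. = FALSE)
  }
  bounds <- .compartment_bounds(R_mm, cfg, tissue)
  sig <- c(blood = tissue$sigma_blood_S_per_m,
           muscle = tissue$sigma_muscle_S_per_m,
           background = tissue$sigma_background_S_per_m)
  comp <- function(name) {
    bb <- bounds[[name]]
    s <- sig[[name]]
    if (s == 0 || all(bb[, 1] == bb[, 2])) return(rep_len(0, length(R_mm)))
    if (acm == "lead") {
      ic <- lead_currents(cfg, s, bb[, 1], bb[, 2])
      lead_compartment_conductance(ic$I_d_A, ic$I_L_A, v_all(cfg))
    } else if (acm == "plate" && name == "blood") {
      G <- rep_len(0, length(R_mm))
      pos <- R_mm > cfg$r0_mm
      G[pos] <- plate_blood_conductance(R_mm[pos], cfg, s, warn = FALSE)
      G
    } else {
      annulus_conductance(bb[, 1], bb[, 2], cfg, s)
    }
  }
  G_bl <- comp("blood"); G_m <- comp("muscle"); G_ba <- comp("background")
  valid <- if (acm == "plate") R_mm < cfg$L_mm else rep(TRUE, length(R_mm))
  tibble::tibble(
    acm = acm,
    R_mm = R_mm,
    G_blood_S = G_bl,
    G_muscle_S = G_m,
    G_background_S = G_ba,
    G_total_S = G_bl + G_m + G_ba,
    in_validity = valid
  )
}

#' @rdname acm_conductance
#' @export
acm_total_conductance <- function(R_mm, cfg, tissue, acm) {
  acm_conductance(R_mm, cfg, tissue, acm)$G_total_S
}
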