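#' Electric field of an axial two-point-charge (dipole) source
#'
#' Builds the superposed field of two opposite point charges at
#' `z = +spacing/2` and `z = -spacing/2` on the catheter axis, the source
#' configuration of the classical conductance model. The source strength is
#' parameterised as `k = V0 * r0` (the charge term `Q/(4*pi*eps)` of a sphere
#' of radius `r0` held at potential `V0`).
#'
#' The returned object is a field function plus metadata (charge locations)
#' used by the quadrature routines [numeric_current()] and
#' [numeric_voltage()]. Evaluate it at points with [field_eval()].
#'
#' @param cfg An [electrode_config()].
#' @param spacing_mm Charge separation (mm). Defaults to the injection
#'   spacing `cfg$d_mm`; pass `cfg$L_mm` to obtain the measurement-field
#'   (lead) configuration.
#' @param V0 Drive potential of the electrode spheres (V).
#'
#' @return An object of class `lv_field`.
#' @seealso [field_plate()], [field_eval()]
#' @examples
#' f <- field_dipole(electrode_config())
#' field_eval(f, rho_mm = 5, z_mm = 0)
#' @export
field_dipole <- function(cfg, spacing_mm = cfg$d_mm, V0 = 1) {
  .assert_cfg(cfg)
  stopifnot(is.numeric(spacing_mm), length(spacing_mm) == 1L, spacing_mm > 0,
            is.numeric(V0), length(V0) == 1L, V0 > 0)
  k <- V0 * .mm(cfg$r0_mm)   # V * m
  s <- .mm(spacing_mm)
  fn <- function(rho_m, z_m) {
    dp <- ((z_m - s / 2)^2 + rho_m^2)^1.5
    dm <- ((z_m + s / 2)^2 + rho_m^2)^1.5
    list(
      Ez  = k * ((z_m - s / 2) / dp - (z_m + s / 2) / dm),
      Erho = k * (rho_m / dp - rho_m / dm)
    )
  }
  new_field(fn,
            charges = data.frame(z_m = c(s / 2, -s / 2), k = c(k, -k)),
            breakpoints_m = numeric(0),
            axis_smooth = function(z) rep_len(0, length(z)),
            label = sprintf("dipole(spacing = %g mm)", spacing_mm))
}

#' Electric field of the sphere-plus-charged-plate superposition
#'
#' Field compression at the blood-muscle boundary is emulated by replacing
#' one point charge with a uniformly charged disc ("plate") of radius `R_mm`
#' (the cavity cross-section) at `z = 0`, superposed with the field of a
#' single charged sphere at `z = +d/2`. The plate carries the same charge
#' magnitude as the sphere (`k = V0 * r0`), spread uniformly, and its field
#' is purely axial:
#' `E_z = k * (2/R^2) * (sign(z) - z / sqrt(z^2 + R^2))`.
#'
#' The sphere term uses the on-axis point-charge form of the dipole field
#' (one charge of the pair); the combination is certified against the
#' quadrature oracle by the package tests.
#'
#' @inheritParams field_dipole
#' @param R_mm Plate (cavity) radius (mm); must exceed `cfg$r0_mm`.
#'
#' @return An object of class `lv_field`.
#' @examples
#' f <- field_plate(electrode_config(), R_mm = 15)
#' field_eval(f, rho_mm = 5, z_mm = 0)
#' @export
field_plate <- function(cfg, R_mm, V0 = 1) {
  .assert_cfg(cfg)
  stopifnot(is.numeric(R_mm), length(R_mm) == 1L,
            is.numeric(V0), length(V0) == 1L, V0 > 0)
  if (R_mm <= cfg$r0_mm) {
    stop("field_plate: plate radius R_mm must exceed the electrode radius r0_mm",
         call. = FALSE)
  }
  k <- V0 * .mm(cfg$r0_mm)
  d <- .mm(cfg$d_mm)
  R <- .mm(R_mm)
  # E = -k * (sphere term - plate term); at z = 0 the plate term takes its
  # z -> 0+ one-sided value (the current plane is approached from above).
  fn <- function(rho_m, z_m) {
    ds <- ((z_m - d / 2)^2 + rho_m^2)^1.5
    sgn <- ifelse(z_m >= 0, 1, -1)
    plate <- (2 / R^2) * (sgn - z_m / sqrt(z_m^2 + R^2))
    list(
      Ez  = -k * (z_m - d / 2) / ds + k * plate,
      Erho = -k * rho_m / ds
    )
  }
  new_field(fn,
            charges = data.frame(z_m = d / 2, k = -k),
            breakpoints_m = 0,
            axis_smooth = function(z) {
              sgn <- ifelse(z >= 0, 1, -1)
              k * (2 / R^2) * (sgn - z / sqrt(z^2 + R^2))
            },
            label = sprintf("sphere+plate(R = %g mm)", R_mm))
}

new_field <- function(fn, charges, breakpoints_m, axis_smooth, label) {
  structure(list(fn = fn, charges = charges,
                 breakpoints_m = breakpoints_m, axis_smooth = axis_smooth,
                 label = label),
            class = "lv_field")
}

# On-axis E_z assembled from the point-charge terms plus the smooth axial
# remainder; `exclude` drops one charge's own (singular) term, which is what
# makes the principal-value window integrand regular without any floating
# point cancellation.
.axis_Ez <- function(field, z, exclude = 0L) {
  out <- field$axis_smooth(z)
  ch <- field$charges
  for (i in seq_len(nrow(ch))) {
    if (i == exclude) next
    dz <- z - ch$z_m[i]
    out <- out + ch$k[i] * sign(dz) / dz^2
  }
  out
}

#' @export
print.lv_field <- function(x, ...) {
  cat("<electric field:", x$label, ">\n")
  invisible(x)
}

.assert_field <- function(field) {
  if (!inherits(field, "lv_field")) {
    stop("expected an `lv_field` (see field_dipole() / field_plate())",
         call. = FALSE)
  }
  invisible(field)
}

#' Evaluate a field at cylindrical coordinates
#'
#' Azimuthal symmetry is assumed throughout, so a point is `(rho, z)`.
#' Evaluation at (or numerically on top of) a point-charge location is a
#' non-integrable singularity and raises an error.
#'
#' @param field An `lv_field` from [field_dipole()] or [field_plate()].
#' @param rho_mm,z_mm Coordinates (mm); vectors are recycled to a common
#'   length. `rho_mm` must be `>= 0`.
#'
#' @return A tibble with columns `rho_mm`, `z_mm`, `E_z`, `E_rho` (V/m).
#' @export
field_eval <- function(field, rho_mm, z_mm) {
  .assert_field(field)
  n <- max(length(rho_mm), length(z_mm))
  rho_mm <- rep_len(rho_mm, n)
  z_mm <- rep_len(z_mm, n)
  if (any(rho_mm < 0)) stop("field_eval: rho_mm must be >= 0", call. = FALSE)
  rho <- .mm(rho_mm); z <- .mm(z_mm)
  for (zc in field$charges$z_m) {
    d2 <- (z - zc)^2 + rho^2
    if (any(d2 < 1e-24)) {
      stop(sprintf("field_eval: point coincides with a charge at z = %g mm (non-integrable singularity)",
                   zc * 1e3), call. = FALSE)
    }
  }
  e <- field$fn(rho, z)
  tibble::tibble(rho_mm = rho_mm, z_mm = z_mm, E_z = e$Ez, E_rho = e$Erho)
}

# Adaptive quadrature wrapper: errors (naming the integrand and interval)
# instead of returning a silently unconverged value. Absolute floor avoids
# spurious failures on near-zero integrals.
.quad <- function(f, lower, upper, what, rel.tol = 1e-10) {
  out <- tryCatch(
    stats::integrate(f, lower, upper, rel.tol = rel.tol, abs.tol = 1e-15,
                     subdivisions = 500L, stop.on.error = FALSE),
    error = function(e) e
  )
  if (inherits(out, "error")) {
    stop(sprintf("quadrature failed for %s on [%g, %g]: %s",
                 what, lower, upper, conditionMessage(out)), call. = FALSE)
  }
  if (out$message != "OK") {
    stop(sprintf("quadrature did not converge for %s on [%g, %g]: %s",
                 what, lower, upper, out$message), call. = FALSE)
  }
  out$value
}

#' Numerically integrated current through the z = 0 plane
#'
#' The quadrature oracle for the model currents: integrates the axial current
#' density `sigma * E_z` over an annulus of the `z = 0` plane,
#' `I = 2 * pi * sigma * integral( E_z(rho, 0) * rho drho )` from
#' `rho_in_mm` to `rho_out_mm`, by adaptive quadrature (relative tolerance
#' 1e-10 requested). Independent of every closed-form conductance expression
#' in the package; used to certify them.
#'
#' @param field An `lv_field`.
#' @param sigma Conductivity of the annulus (S/m).
#' @param rho_in_mm,rho_out_mm Inner and outer annulus radii (mm),
#'   `rho_in_mm <= rho_out_mm`. `rho_out_mm` may be `Inf`.
#'
#' @return Current in amperes (signed).
#' @examples
#' cfg <- electrode_config()
#' numeric_current(field_dipole(cfg), sigma = 0.7,
#'                 rho_in_mm = cfg$r0_mm, rho_out_mm = 20)
#' @export
numeric_current <- function(field, sigma, rho_in_mm, rho_out_mm) {
  .assert_field(field)
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  if (!is.finite(rho_in_mm) || rho_in_mm < 0 || is.na(rho_out_mm)) {
    stop("numeric_current: invalid annulus bounds", call. = FALSE)
  }
  if (rho_in_mm > rho_out_mm) {
    stop("numeric_current: rho_in_mm must be <= rho_out_mm", call. = FALSE)
  }
  if (rho_in_mm == rho_out_mm || sigma == 0) return(0)
  a <- .mm(rho_in_mm)
  b <- if (is.finite(rho_out_mm)) .mm(rho_out_mm) else Inf
  2 * pi * sigma *
    .quad(function(r) field$fn(r, rep_len(0, length(r)))$Ez * r, a, b,
          what = sprintf("current density of %s", field$label))
}

#' Numerically integrated on-axis voltage
#'
#' The quadrature oracle for the model voltages:
#' `V = -integral( E_z(0, z) dz )` from `z_a_mm` to `z_b_mm` along the axis,
#' by adaptive quadrature. If the segment crosses an on-axis point charge the
#' integral is taken in the Cauchy principal-value sense: a symmetric window
#' around the charge is integrated as the pair `E(z0+u) + E(z0-u)` with the
#' crossed charge's own term dropped - that term's symmetric principal value
#' vanishes identically, and the remaining pair integrand is regular - which
#' recovers the potential difference between the endpoints. A charge lying
#' numerically on an endpoint is a non-integrable configuration and raises
#' an error.
#'
#' @param field An `lv_field`.
#' @param z_a_mm,z_b_mm Endpoints of the axial path (mm). Reversing the path
#'   flips the sign.
#'
#' @return Potential difference in volts (signed).
#' @examples
#' cfg <- electrode_config()
#' numeric_voltage(field_dipole(cfg), -cfg$L_mm / 2, cfg$L_mm / 2)
#' @export
numeric_voltage <- function(field, z_a_mm, z_b_mm) {
  .assert_field(field)
  stopifnot(is.finite(z_a_mm), is.finite(z_b_mm))
  if (z_a_mm == z_b_mm) return(0)
  if (z_a_mm > z_b_mm) return(-numeric_voltage(field, z_b_mm, z_a_mm))
  a <- .mm(z_a_mm); b <- .mm(z_b_mm)
  fz <- function(z) .axis_Ez(field, z)
  ch <- field$charges
  tol <- 1e-12 * max(1, abs(a), abs(b))
  if (any(abs(ch$z_m - a) < tol | abs(ch$z_m - b) < tol)) {
    stop("numeric_voltage: a charge lies on an endpoint of the path (non-integrable)",
         call. = FALSE)
  }
  inside <- ch[ch$z_m > a & ch$z_m < b, , drop = FALSE]
  inside <- inside[order(inside$z_m), , drop = FALSE]
  cuts <- sort(field$breakpoints_m[field$breakpoints_m > a & field$breakpoints_m < b])
  what <- sprintf("on-axis field of %s", field$label)
  total <- 0
  lo <- a
  if (nrow(inside)) {
    neigh <- c(a, inside$z_m, b)
    for (i in seq_len(nrow(inside))) {
      z0 <- inside$z_m[i]
      j <- which(abs(ch$z_m - z0) < tol)[1]
      w <- 0.45 * min(z0 - neigh[i], neigh[i + 2] - z0)
      seg_cuts <- cuts[cuts > lo & cuts < z0 - w]
      for (cc in c(seg_cuts, z0 - w)) {
        total <- total + .quad(fz, lo, cc, what)
        lo <- cc
      }
      # paired principal value around the charge: the excluded charge's own
      # term has an exactly vanishing symmetric principal value, and the
      # remaining integrand is regular
      pair <- function(u) {
        .axis_Ez(field, z0 + u, exclude = j) +
          .axis_Ez(field, z0 - u, exclude = j)
      }
      total <- total + .quad(pair, 0, w, what)
      lo <- z0 + w
    }
  }
  seg_cuts <- cuts[cuts > lo & cuts < b]
  for (cc in c(seg_cuts, b)) {
    total <- total + .quad(fz, lo, cc, what)
    lo <- cc
  }
  -total
}
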