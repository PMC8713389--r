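# Shared fixtures for the test suite.

default_cfg <- function() electrode_config(r0_mm = 1, d_mm = 40, L_mm = 20)

phantom_tissue <- function() {
  tissue_model(0.7, 0.3, 0.2, wall_thickness_mm = 10,
               background_outer_radius_mm = 200)
}

saline_tissue <- function(sigma = 0.7) tissue_model(sigma)

# A grid of valid geometries for property-style checks.
cfg_grid <- function() {
  list(
    electrode_config(1, 40, 20),
    electrode_config(0.5, 30, 12),
    electrode_config(2, 60, 25),
    electrode_config(1.5, 50, 10),
    electrode_config(0.8, 25, 18)
  )
}

# Oracle-side conductance: current and voltage both by quadrature on the
# defining fields, never through the closed forms.
oracle_wei_G <- function(R_mm, cfg, sigma, R_in_mm = cfg$r0_mm) {
  f <- field_dipole(cfg)
  I <- numeric_current(f, sigma, R_in_mm, R_mm)
  V <- numeric_voltage(f, -cfg$L_mm / 2, cfg$L_mm / 2)
  abs(I / V)
}

oracle_plate_G <- function(R_mm, cfg, sigma) {
  f <- field_plate(cfg, R_mm)
  I <- numeric_current(f, sigma, cfg$r0_mm, R_mm)
  V <- 2 * numeric_voltage(f, 0, cfg$L_mm / 2)
  abs(I / V)
}

oracle_lead_G <- function(R_mm, cfg, sigma, R_in_mm = cfg$r0_mm) {
  fd <- field_dipole(cfg, cfg$d_mm)
  fL <- field_dipole(cfg, cfg$L_mm)
  I_d <- numeric_current(fd, sigma, R_in_mm, R_mm)
  I_L <- numeric_current(fL, sigma, R_in_mm, R_mm)
  V <- numeric_voltage(fd, -cfg$L_mm / 2, cfg$L_mm / 2)
  sqrt(abs(I_d * I_L)) / abs(V)
}
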