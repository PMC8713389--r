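test_that("dipole field has the symmetries of an axial charge pair", {
  cfg <- default_cfg()
  f <- field_dipole(cfg)
  # on-axis radial component vanishes
  e0 <- field_eval(f, rho_mm = 0, z_mm = c(-7, 0, 3))
  expect_equal(e0$E_rho, c(0, 0, 0))
  # E_z even in z, E_rho odd in z
  ep <- field_eval(f, rho_mm = c(3, 8), z_mm = c(5, 12))
  em <- field_eval(f, rho_mm = c(3, 8), z_mm = c(-5, -12))
  expect_equal(em$E_z, ep$E_z)
  expect_equal(em$E_rho, -ep$E_rho)
})

test_that("dipole field matches an independent term-by-term evaluation", {
  cfg <- default_cfg()
  f <- field_dipole(cfg) # V0 = 1, so k = r0 = 1 mm = 1e-3 V*m
  rho <- 5e-3; z <- 0; s <- 40e-3; k <- 1e-3
  expected_Ez <- k * ((z - s / 2) / ((z - s / 2)^2 + rho^2)^1.5 -
                        (z + s / 2) / ((z + s / 2)^2 + rho^2)^1.5)
  got <- field_eval(f, rho_mm = 5, z_mm = 0)
  expect_equal(got$E_z, expected_Ez, tolerance = 1e-12)
  expect_equal(got$E_rho, 0, tolerance = 1e-15) # rho terms cancel at z = 0
})

test_that("plate field combines sphere and plate terms as specified", {
  cfg <- default_cfg()
  R <- 15
  f <- field_plate(cfg, R_mm = R)
  k <- 1e-3; d <- 40e-3; Rm <- 15e-3
  # plate term alone is axial: at large rho the sphere term decays, but
  # check the full field on-axis against term-by-term evaluation at z = L/4
  z <- 5e-3
  expected <- -k * (z - d / 2) / ((z - d / 2)^2)^1.5 +
    k * (2 / Rm^2) * (1 - z / sqrt(z^2 + Rm^2))
  expect_equal(field_eval(f, 0, 5)$E_z, expected, tolerance = 1e-12)
  # plate term at z = 0+ is k * 2 / R^2 on top of the sphere term
  sphere0 <- k * (d / 2) / ((d / 2)^2 + 0)^1.5
  expect_equal(field_eval(f, 0, 0)$E_z, sphere0 + k * 2 / Rm^2,
               tolerance = 1e-12)
})

test_that("fields vanish far away and error on charge locations", {
  cfg <- default_cfg()
  far <- 1e4 * cfg$d_mm
  near <- abs(field_eval(field_dipole(cfg), 5, 0)$E_z)
  for (f in list(field_dipole(cfg), field_plate(cfg, 15))) {
    expect_lt(abs(field_eval(f, 0, far)$E_z), 1e-9 * near)
  }
  # radial decay of the dipole (the plate term is axial and rho-independent
  # by construction, so only the charge-pair field decays radially)
  expect_lt(abs(field_eval(field_dipole(cfg), far, 0)$E_z), 1e-12 * near)
  expect_error(field_eval(field_dipole(cfg), 0, cfg$d_mm / 2),
               "singular")
})

test_that("numeric current: empty domain, linearity, closed-form match", {
  cfg <- default_cfg()
  f <- field_dipole(cfg)
  expect_identical(numeric_current(f, 0.7, 10, 10), 0)
  I1 <- numeric_current(f, 0.7, cfg$r0_mm, 20)
  I2 <- numeric_current(f, 1.4, cfg$r0_mm, 20)
  expect_equal(I2, 2 * I1, tolerance = 1e-12)
  # against independent evaluation of the integrated dipole current
  k <- 1e-3; d <- 40e-3
  expected <- -4 * pi * 0.7 * k * d *
    (1 / sqrt(d^2 + 4 * (1e-3)^2) - 1 / sqrt(d^2 + 4 * (20e-3)^2))
  expect_equal(I1, expected, tolerance = 1e-8)
  expect_error(numeric_current(f, 0.7, 20, 10), "<=")
})

test_that("numeric voltage: orientation, degenerate path, closed-form match", {
  cfg <- default_cfg()
  f <- field_dipole(cfg)
  expect_identical(numeric_voltage(f, 4, 4), 0)
  V <- numeric_voltage(f, -cfg$L_mm / 2, cfg$L_mm / 2)
  expect_equal(numeric_voltage(f, cfg$L_mm / 2, -cfg$L_mm / 2), -V,
               tolerance = 1e-12)
  k <- 1e-3; d <- 40e-3; L <- 20e-3
  expect_equal(abs(V), 8 * k * L / (d^2 - L^2), tolerance = 1e-9)
})

test_that("principal-value path through the charges recovers reciprocity", {
  # voltage of the L-spacing dipole across the d-spacing pair crosses both
  # charges; its principal value must equal the uncrossed d-dipole voltage
  for (cfg in cfg_grid()) {
    V_d <- numeric_voltage(field_dipole(cfg, cfg$d_mm),
                           -cfg$L_mm / 2, cfg$L_mm / 2)
    V_L <- numeric_voltage(field_dipole(cfg, cfg$L_mm),
                           -cfg$d_mm / 2, cfg$d_mm / 2)
    expect_equal(V_L, V_d, tolerance = 1e-10)
  }
  # a charge on an endpoint is non-integrable
  cfg <- default_cfg()
  expect_error(numeric_voltage(field_dipole(cfg), 0, cfg$d_mm / 2),
               "endpoint")
})

test_that("oracle agrees with every closed-form conductance on a grid", {
  for (cfg in cfg_grid()[1:3]) {
    for (R in c(cfg$L_mm * 0.4, cfg$L_mm * 0.75, cfg$d_mm)) {
      expect_equal(oracle_wei_G(R, cfg, 0.7),
                   wei_conductance(R, cfg, 0.7), tolerance = 1e-6)
      expect_equal(oracle_lead_G(R, cfg, 0.7),
                   acm_conductance(R, cfg, saline_tissue(), "lead")$G_blood_S,
                   tolerance = 1e-6)
      if (R < cfg$L_mm) {
        expect_equal(oracle_plate_G(R, cfg, 0.7),
                     plate_blood_conductance(R, cfg, 0.7), tolerance = 1e-6)
      }
    }
    # annulus extension against the oracle on the same annulus
    expect_equal(
      abs(numeric_current(field_dipole(cfg), 0.17, 20, 30) /
            numeric_voltage(field_dipole(cfg), -cfg$L_mm / 2, cfg$L_mm / 2)),
      annulus_conductance(20, 30, cfg, 0.17), tolerance = 1e-6)
  }
})
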