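test_that("geometry invariants are enforced", {
  expect_error(electrode_config(r0_mm = 0), "r0_mm")
  expect_error(electrode_config(r0_mm = 1, d_mm = 20, L_mm = 40), "L_mm < d_mm")
  expect_error(electrode_config(r0_mm = 12, d_mm = 40, L_mm = 20), "r0_mm <")
  expect_error(tissue_model(-1), ">= 0")
  expect_error(tissue_model(0.7, wall_thickness_mm = -2), "wall_thickness")
})

test_that("all ACM blood conductances vanish at the electrode radius", {
  for (cfg in cfg_grid()) {
    expect_identical(wei_conductance(cfg$r0_mm, cfg, 0.7), 0)
    ic <- lead_currents(cfg, 0.7, cfg$r0_mm, cfg$r0_mm)
    expect_identical(lead_compartment_conductance(ic$I_d_A, ic$I_L_A,
                                                  v_all(cfg)), 0)
    bd <- acm_conductance(cfg$r0_mm, cfg, saline_tissue(), "plate")
    expect_identical(bd$G_blood_S, 0)
  }
})

test_that("wei conductance is increasing, bounded by its infinite-pool limit", {
  cfg <- default_cfg()
  R <- seq(cfg$r0_mm + 0.1, 80, length.out = 400)
  G <- wei_conductance(R, cfg, 0.7)
  expect_true(all(diff(G) > 0))
  d <- 40e-3; L <- 20e-3; r0 <- 1e-3
  G_inf <- pi * 0.7 * d * (d^2 - L^2) / (2 * L) / sqrt(d^2 + 4 * r0^2)
  expect_true(all(G < G_inf))
  expect_equal(wei_conductance(Inf, cfg, 0.7), G_inf, tolerance = 1e-12)
  expect_error(wei_conductance(0.5, cfg, 0.7), "r0")
})

test_that("annulus conductance telescopes exactly and checks its bounds", {
  cfg <- default_cfg()
  g <- function(a, b) annulus_conductance(a, b, cfg, 0.17)
  expect_identical(g(20, 20), 0)
  expect_equal(g(5, 20) + g(20, 60), g(5, 60), tolerance = 1e-15)
  # an unbounded background is the limit of a very distant outer radius
  expect_equal(g(20, Inf), g(20, 1e6), tolerance = 1e-4)
  expect_gt(g(20, Inf), g(20, 1e6))
  expect_error(g(30, 20), "R_in")
})

test_that("plate blood conductance is monotone and warns beyond validity", {
  cfg <- default_cfg()
  R <- seq(cfg$r0_mm + 0.1, cfg$L_mm - 0.1, length.out = 200)
  G <- plate_blood_conductance(R, cfg, 0.7)
  expect_true(all(diff(G) > 0))
  expect_warning(plate_blood_conductance(25, cfg, 0.7), "validity")
  expect_error(plate_blood_conductance(0.5, cfg, 0.7), "r0")
  bd <- acm_conductance(c(15, 25), cfg, saline_tissue(), "plate")
  expect_identical(bd$in_validity, c(TRUE, FALSE))
})

test_that("lead currents swap with the spacings and match signs", {
  cfg <- default_cfg()
  ic <- lead_currents(cfg, 0.7, 1, 20)
  swapped <- lead_currents(lvcond:::swap_injection_measurement(cfg), 0.7, 1, 20)
  expect_equal(ic$I_d_A, swapped$I_L_A, tolerance = 1e-15)
  expect_equal(ic$I_L_A, swapped$I_d_A, tolerance = 1e-15)
  expect_true(all(c(ic$I_d_A, ic$I_L_A) < 0))
  expect_error(lead_currents(cfg, 0.7, 20, 10), "rho_in")
})

test_that("lead compartment conductance: degenerate and invalid inputs", {
  V <- 0.1
  expect_equal(lead_compartment_conductance(-2e-3, -2e-3, V), 2e-3 / V)
  expect_identical(lead_compartment_conductance(0, -1e-3, V), 0)
  expect_error(lead_compartment_conductance(1e-3, -1e-3, V), "opposite")
})

test_that("lead total conductance is reciprocal: invariant under d <-> L", {
  tis <- phantom_tissue()
  for (cfg in cfg_grid()) {
    swapped <- lvcond:::swap_injection_measurement(cfg)
    for (R in c(8, 15, 35)) {
      expect_equal(acm_total_conductance(R, cfg, tis, "lead"),
                   acm_total_conductance(R, swapped, tis, "lead"),
                   tolerance = 1e-15)
    }
  }
})

test_that("compartment conductances are non-negative and sum exactly", {
  cfg <- default_cfg()
  tis <- phantom_tissue()
  for (acm in c("wei", "plate", "lead")) {
    bd <- suppressWarnings(acm_conductance(c(5, 12, 19, 30), cfg, tis, acm))
    expect_true(all(bd$G_blood_S >= 0 & bd$G_muscle_S >= 0 &
                      bd$G_background_S >= 0))
    expect_identical(bd$G_total_S,
                     bd$G_blood_S + bd$G_muscle_S + bd$G_background_S)
  }
})

test_that("insulating surround reduces totals to the blood term", {
  cfg <- default_cfg()
  tis0 <- tissue_model(0.7, 0, 0)
  for (acm in c("wei", "plate", "lead")) {
    bd <- acm_conductance(15, cfg, tis0, acm)
    expect_identical(bd$G_total_S, bd$G_blood_S)
  }
  # zero wall thickness removes the muscle term even when conductive
  tis_b0 <- tissue_model(0.7, 0.3, 0, wall_thickness_mm = 0)
  bd <- acm_conductance(15, cfg, tis_b0, "plate")
  expect_identical(bd$G_muscle_S, 0)
})

test_that("lead blood term equals its explicit closed-form combination", {
  cfg <- default_cfg()
  ic <- lead_currents(cfg, 0.7, cfg$r0_mm, 20)
  G_direct <- sqrt(abs(ic$I_d_A * ic$I_L_A)) / v_all(cfg)
  expect_equal(acm_conductance(20, cfg, saline_tissue(), "lead")$G_blood_S,
               G_direct, tolerance = 1e-15)
})

test_that("classical inversion of lead-generated conductance overestimates", {
  # conductive surround: total lead conductance read as if it were a pure
  # blood pool (classical insulating assumption) implies a larger radius
  cfg <- default_cfg()
  tis <- phantom_tissue()
  for (R in c(11.3, 15, 19.94)) {
    G_lead <- acm_total_conductance(R, cfg, tis, "lead")
    R_hat <- stats::uniroot(function(r) wei_conductance(r, cfg, 0.7) - G_lead,
                            c(cfg$r0_mm + 1e-6, 500))$root
    expect_gt(R_hat, R)
  }
})
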