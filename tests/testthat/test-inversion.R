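test_that("lookup tables sample the forward model and enforce monotonicity", {
  cfg <- default_cfg()
  tab <- build_lookup_table("wei", cfg, tissue_model(0.7), n = 100)
  expect_s3_class(tab, "lv_lookup")
  expect_equal(tab$conductance_S, wei_conductance(tab$radius_mm, cfg, 0.7),
               tolerance = 1e-15)
  expect_true(all(diff(tab$radius_mm) > 0))
  expect_true(all(diff(tab$conductance_S) > 0))
  # two-point table is legal
  tab2 <- build_lookup_table("wei", cfg, tissue_model(0.7), n = 2)
  expect_identical(nrow(tab2), 2L)
  expect_error(build_lookup_table("wei", cfg, tissue_model(0.7),
                                  R_min_mm = 0.5), "R_min")
  # a non-monotone sampled map is rejected, naming the interval
  expect_error(
    lvcond:::new_lookup_table(function(R) sin(R / 5), "wei", cfg,
                              tissue_model(0.7), 2, 80, 200),
    "not strictly increasing on"
  )
})

test_that("plate grids beyond the measurement spacing follow the policy", {
  cfg <- default_cfg()
  tis <- tissue_model(0.7)
  expect_warning(build_lookup_table("plate", cfg, tis, n = 60),
                 "validity")
  expect_error(build_lookup_table("plate", cfg, tis, n = 60,
                                  plate_policy = "error"), "validity")
  tr <- build_lookup_table("plate", cfg, tis, n = 60,
                           plate_policy = "truncate")
  expect_lte(max(tr$radius_mm), cfg$L_mm)
})

test_that("inversion is exact at knots, clamps out of range, flags it", {
  cfg <- default_cfg()
  tab <- build_lookup_table("lead", cfg, phantom_tissue(), n = 300)
  k <- c(1L, 57L, 300L)
  est <- radius_from_conductance(tab$conductance_S[k], tab)
  expect_equal(est$radius_mm, tab$radius_mm[k], tolerance = 1e-12)
  expect_true(all(est$in_range))
  below <- radius_from_conductance(tab$conductance_S[1] * 0.5, tab)
  above <- radius_from_conductance(tab$conductance_S[300] * 1.5, tab)
  expect_identical(below$radius_mm, tab$radius_mm[1])
  expect_identical(above$radius_mm, tab$radius_mm[300])
  expect_false(below$in_range || above$in_range)
  expect_error(radius_from_conductance(NaN, tab), "finite")
})

test_that("round-trip error is within 0.01 mm and shrinks with refinement", {
  cfg <- default_cfg()
  tis <- phantom_tissue()
  set.seed(42)
  R_true <- runif(100, 2.5, 79)
  errs <- sapply(c("wei", "plate", "lead"), function(acm) {
    tab <- suppressWarnings(build_lookup_table(acm, cfg, tis, n = 2000))
    G <- acm_total_conductance(R_true, cfg, tis, acm)
    max(abs(radius_from_conductance(G, tab)$radius_mm - R_true))
  })
  expect_true(all(errs <= 0.01))
  # refinement convergence on the lead model
  err_at <- function(n) {
    tab <- build_lookup_table("lead", cfg, tis, n = n)
    G <- acm_total_conductance(R_true, cfg, tis, "lead")
    max(abs(radius_from_conductance(G, tab)$radius_mm - R_true))
  }
  e <- c(err_at(250), err_at(500), err_at(1000))
  expect_true(all(diff(e) <= 0))
})

test_that("estimated radius is non-decreasing in conductance", {
  cfg <- default_cfg()
  tab <- build_lookup_table("lead", cfg, saline_tissue(1.68), n = 500)
  G <- seq(min(tab$conductance_S), max(tab$conductance_S), length.out = 400)
  R <- radius_from_conductance(G, tab)$radius_mm
  expect_true(all(diff(R) >= 0))
})

test_that("lookup CSV round-trips values and metadata exactly", {
  cfg <- electrode_config(1.25, 45, 18)
  tis <- tissue_model(0.72, 0.31, 0.21, 9, 180)
  tab <- build_lookup_table("lead", cfg, tis, n = 50)
  path <- withr::local_tempfile(fileext = ".csv")
  write_lookup_csv(tab, path)
  back <- read_lookup_csv(path)
  expect_identical(back$radius_mm, tab$radius_mm)
  expect_identical(back$conductance_S, tab$conductance_S)
  expect_identical(attr(back, "acm"), "lead")
  expect_equal(attr(back, "cfg"), cfg)
  expect_equal(attr(back, "tissue"), tis)
  # a re-read table inverts identically
  G <- acm_total_conductance(30, cfg, tis, "lead")
  expect_identical(radius_from_conductance(G, back)$radius_mm,
                   radius_from_conductance(G, tab)$radius_mm)
})

test_that("estimate_radius appends radius and volume columns to any frame", {
  cfg <- default_cfg()
  tab <- build_lookup_table("wei", cfg, tissue_model(0.7), n = 500)
  dat <- tibble::tibble(id = c("a", "b"),
                        conductance_S = wei_conductance(c(15, 25), cfg, 0.7))
  out <- estimate_radius(dat, tab, volume_model = "wyatt", length_mm = 80)
  expect_named(out, c("id", "conductance_S", "radius_mm", "in_range",
                      "volume_mL"))
  expect_equal(out$radius_mm, c(15, 25), tolerance = 1e-4)
  expect_equal(out$volume_mL, wyatt_volume(out$radius_mm, 80))
  expect_error(estimate_radius(dat, tab, conductance_col = "nope"), "nope")
  expect_error(estimate_radius(dat, tab, volume_model = "wyatt"), "length_mm")
})
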