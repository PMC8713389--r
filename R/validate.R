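# Closed-loop and cross-model validation: simulate measurements on a
# fixture series with one forward model, invert them with a (possibly
# different) model, and summarise agreement against the reference radii.

#' Simulate-invert-compare validation run
#'
#' Generates conductances on a fixture series with `generate_acm`, inverts
#' them through a lookup table built for `invert_acm`, and computes the
#' radius-normalised Bland-Altman agreement against the fixtures' reference
#' radii. With `invert_acm == generate_acm`, matching tissue and zero noise
#' this is a closed loop and recovers the radii to interpolation accuracy.
#' Passing `invert_tissue` allows model-mismatch experiments, e.g.
#' inverting conductances from a conductive surround with the classical
#' model's insulating assumption.
#'
#' All fixtures in `fixtures` must share one tissue model (one lookup table
#' serves the whole series).
#'
#' @param fixtures A fixture tibble ([glass_container_fixtures()] /
#'   [phantom_fixtures()]).
#' @param generate_acm Forward model generating the measurements.
#' @param invert_acm Model used for inversion (default: same).
#' @param cfg An [electrode_config()].
#' @param n Measurements per fixture.
#' @param noise_sd_relative Relative measurement noise SD.
#' @param seed Integer seed for the noise.
#' @param invert_tissue `NULL` to invert with the fixtures' own tissue
#'   model, or an [tissue_model()] to invert under different assumptions.
#' @param table_n Lookup-table grid size.
#' @param R_min_mm,R_max_mm Lookup grid bounds (mm). The default lower bound
#'   is half the smallest reference radius (but at least `r0 + 0.5`): the
#'   table spans the band of plausible radii rather than reaching down to
#'   the catheter surface, where conductive-background totals can lose
#'   monotonicity without ever being of interest.
#'
#' @return An object of class `lv_validation`: list with `measurements`
#'   (per-measurement tibble incl. estimates), `per_fixture` (summary
#'   tibble), `agreement` (an `lv_agreement`), and the run parameters.
#'   Has `tidy()`, `glance()` and `autoplot()` methods.
#' @examples
#' fx <- glass_container_fixtures(1.68)
#' run_validation(fx, "lead", cfg = electrode_config(), n = 20,
#'                noise_sd_relative = 0, seed = 1, table_n = 400)
#' @export
run_validation <- function(fixtures, generate_acm,
                           invert_acm = generate_acm, cfg = electrode_config(),
                           n = 100, noise_sd_relative = 0.02, seed = 1,
                           invert_tissue = NULL, table_n = 2000,
                           R_min_mm = NULL, R_max_mm = 80) {
  stopifnot(is.data.frame(fixtures), nrow(fixtures) >= 1L)
  .assert_cfg(cfg)
  generate_acm <- match.arg(generate_acm, c("wei", "plate", "lead"))
  invert_acm <- match.arg(invert_acm, c("wei", "plate", "lead"))
  tis_cols <- c("sigma_blood_S_per_m", "sigma_muscle_S_per_m",
                "sigma_background_S_per_m", "wall_thickness_mm",
                "background_outer_radius_mm")
  if (nrow(unique(fixtures[tis_cols])) != 1L) {
    stop("run_validation: all fixtures must share one tissue model",
         call. = FALSE)
  }
  tis_fix <- .fixture_tissue(fixtures[1, ])
  tis_inv <- if (is.null(invert_tissue)) tis_fix else {
    .assert_tissue(invert_tissue)
    invert_tissue
  }
  meas <- simulate_measurements(fixtures, generate_acm, cfg, n = n,
                                noise_sd_relative = noise_sd_relative,
                                seed = seed)
  if (is.null(R_min_mm)) {
    R_min_mm <- max(cfg$r0_mm + 0.5, min(fixtures$true_radius_mm) / 2)
  }
  table <- suppressWarnings(
    build_lookup_table(invert_acm, cfg, tis_inv, R_min_mm = R_min_mm,
                       R_max_mm = R_max_mm, n = table_n)
  )
  est <- estimate_radius(meas, table)
  per_fixture <- est |>
    dplyr::group_by(.data$fixture, .data$series, .data$true_radius_mm) |>
    dplyr::summarise(
      mean_radius_mm = mean(.data$radius_mm),
      sd_radius_mm = stats::sd(.data$radius_mm),
      n = dplyr::n(),
      n_out_of_range = sum(!.data$in_range),
      .groups = "drop"
    )
  structure(
    list(measurements = est,
         per_fixture = per_fixture,
         agreement = bias_loa(est$radius_mm, est$true_radius_mm),
         generate_acm = generate_acm,
         invert_acm = invert_acm,
         noise_sd_relative = noise_sd_relative,
         n = n, seed = seed, cfg = cfg,
         tissue = tis_fix, invert_tissue = tis_inv),
    class = "lv_validation"
  )
}

#' @export
print.lv_validation <- function(x, ...) {
  cat(sprintf("<validation run: generated with %s, inverted with %s, noise %.3g, n = %d per fixture>\n",
              x$generate_acm, x$invert_acm, x$noise_sd_relative, x$n))
  print(x$agreement)
  invisible(x)
}

#' @rdname run_validation
#' @param x An `lv_validation`.
#' @param ... Unused.
#' @export
tidy.lv_validation <- function(x, ...) x$per_fixture

#' @rdname run_validation
#' @export
glance.lv_validation <- function(x, ...) {
  dplyr::mutate(glance(x$agreement),
                generate_acm = x$generate_acm, invert_acm = x$invert_acm,
                noise_sd_relative = x$noise_sd_relative, seed = x$seed,
                .before = 1)
}
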