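# Bench-validation fixtures and agreement statistics: the two reference
# setups used to validate the calculation methods (cylindrical glass
# containers filled with saline, and ventricle-shaped silicone phantoms in
# a saline tank), a seeded synthetic-measurement model standing in for raw
# conductance recordings, and Bland-Altman bias / limits-of-agreement
# statistics normalised by the mean reference radius.

#' Glass-container fixtures
#'
#' Five cylindrical glass containers spanning physiological to severely
#' dilated heart radii (13.3 to 50.4 mm), filled with saline of the given
#' conductivity. Glass wall and surroundings are insulating, so muscle and
#' background conductivities are zero. The two bench saline batches are
#' tagged as series `"sigma1"` (1.68 S/m) and `"sigma2"` (0.62 S/m); other
#' conductivities are tagged `"custom"`. (The 1.68 S/m batch is also quoted
#' as 1.69 S/m in one figure of the original bench report; the body-text
#' value 1.68 is used here.)
#'
#' @param sigma_S_per_m Saline conductivity (S/m).
#' @return A tibble of fixtures: `fixture`, `series`, `true_radius_mm`,
#'   `reference_source`, and the tissue-model columns.
#' @examples
#' glass_container_fixtures(1.68)
#' @export
glass_container_fixtures <- function(sigma_S_per_m = 1.68) {
  stopifnot(is.numeric(sigma_S_per_m), length(sigma_S_per_m) == 1L,
            sigma_S_per_m > 0)
  series <- if (isTRUE(all.equal(sigma_S_per_m, 1.68))) "sigma1"
            else if (isTRUE(all.equal(sigma_S_per_m, 0.62))) "sigma2"
            else "custom"
  radii <- c(13.3, 17.5, 32.8, 38.6, 50.4)
  tibble::tibble(
    fixture = sprintf("glass_%d", seq_along(radii)),
    series = series,
    true_radius_mm = radii,
    reference_source = "glass",
    sigma_blood_S_per_m = sigma_S_per_m,
    sigma_muscle_S_per_m = 0,
    sigma_background_S_per_m = 0,
    wall_thickness_mm = 0,
    background_outer_radius_mm = Inf
  )
}

#' CT reference geometry of the ventricle phantom
#'
#' The six filling steps of the silicone ventricle phantom: CT-measured
#' volume, cross-sectional area at the centre electrode pair, and the
#' equivalent circular radius `sqrt(A/pi)` recomputed from the area.
#'
#' @return A tibble with columns `step`, `volume_mL`, `area_mm2`,
#'   `radius_mm`.
#' @examples
#' phantom_ct_reference()
#' @export
phantom_ct_reference <- function() {
  areas <- c(1248.84, 1022.55, 855.50, 683.15, 506.83, 401.12)
  tibble::tibble(
    step = 1:6,
    volume_mL = c(117.90, 107.12, 97.96, 87.20, 76.84, 69.46),
    area_mm2 = areas,
    radius_mm = equivalent_radius_from_area(areas)
  )
}

#' Ventricle-phantom fixtures
#'
#' Six fixtures, one per filling step of the silicone ventricle phantom,
#' with the equivalent circular radii from [phantom_ct_reference()] and the
#' bench conductivities: saline pool 0.7 S/m, background tank 0.2 S/m, and
#' a wall that is either effectively insulating (pure silicone, 1e-6 S/m)
#' or conductive (carbon-doped silicone, 0.3 S/m).
#'
#' @param conductive_wall `TRUE` for the carbon-doped (conductive) phantom
#'   wall, `FALSE` for pure silicone.
#' @param sigma_blood_S_per_m Saline (pool) conductivity (S/m).
#' @param sigma_background_S_per_m Tank (background) conductivity (S/m).
#' @param wall_thickness_mm Phantom wall thickness (mm); not printed for
#'   the bench phantoms, default 10 mm.
#' @param background_outer_radius_mm Outer extent of the tank (mm); default
#'   200 mm (five injection spacings of the default catheter).
#' @return A tibble of fixtures in the same layout as
#'   [glass_container_fixtures()].
#' @examples
#' phantom_fixtures(conductive_wall = TRUE)
#' @export
phantom_fixtures <- function(conductive_wall = TRUE,
                             sigma_blood_S_per_m = 0.7,
                             sigma_background_S_per_m = 0.2,
                             wall_thickness_mm = 10,
                             background_outer_radius_mm = 200) {
  ref <- phantom_ct_reference()
  tibble::tibble(
    fixture = sprintf("phantom_step%d", ref$step),
    series = if (conductive_wall) "phantom_conductive" else "phantom_insulating",
    true_radius_mm = ref$radius_mm,
    reference_source = "phantom_ct",
    sigma_blood_S_per_m = sigma_blood_S_per_m,
    sigma_muscle_S_per_m = if (conductive_wall) 0.3 else 1e-6,
    sigma_background_S_per_m = sigma_background_S_per_m,
    wall_thickness_mm = wall_thickness_mm,
    background_outer_radius_mm = background_outer_radius_mm
  )
}

# Tissue model of one fixture row (fixtures within a series share tissue
# except for nothing - each row carries its own columns).
.fixture_tissue <- function(row) {
  tissue_model(row$sigma_blood_S_per_m, row$sigma_muscle_S_per_m,
               row$sigma_background_S_per_m, row$wall_thickness_mm,
               row$background_outer_radius_mm)
}

#' Simulate conductance measurements for fixtures
#'
#' Synthetic stand-in for raw conductance recordings (which bench studies
#' rarely publish): for each fixture the forward model of the chosen method
#' is evaluated at the true radius and perturbed with multiplicative
#' Gaussian noise, `G_i = G_model * (1 + eps_i)`,
#' `eps_i ~ N(0, noise_sd_relative)`. Multiplicative noise reflects
#' impedance-analyzer noise scaling with signal level. Reproducible given
#' `seed`; the global RNG state is left untouched.
#'
#' @param fixtures A fixture tibble ([glass_container_fixtures()] /
#'   [phantom_fixtures()]).
#' @param acm Forward model used to generate the conductances.
#' @param cfg An [electrode_config()].
#' @param n Measurements per fixture.
#' @param noise_sd_relative Relative noise SD (default 0.02).
#' @param seed Integer seed.
#' @return A tibble with one row per simulated measurement: the fixture
#'   columns plus `conductance_S`, `acm`, `seed`.
#' @examples
#' fx <- glass_container_fixtures(1.68)
#' simulate_measurements(fx, "lead", electrode_config(), n = 3, seed = 1)
#' @export
simulate_measurements <- function(fixtures, acm, cfg, n = 100,
                                  noise_sd_relative = 0.02, seed = 1) {
  stopifnot(is.data.frame(fixtures), nrow(fixtures) >= 1L,
            is.numeric(n), n >= 1, is.numeric(noise_sd_relative),
            noise_sd_relative >= 0)
  .assert_cfg(cfg)
  acm <- match.arg(acm, c("wei", "plate", "lead"))
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(fixtures)), function(i) {
      row <- fixtures[i, ]
      tis <- .fixture_tissue(row)
      G0 <- acm_total_conductance(row$true_radius_mm, cfg, tis, acm)
      eps <- stats::rnorm(n, mean = 0, sd = noise_sd_relative)
      tibble::tibble(
        fixture = row$fixture,
        series = row$series,
        true_radius_mm = row$true_radius_mm,
        conductance_S = G0 * (1 + eps),
        acm = acm,
        seed = seed
      )
    })
  })
}

#' Bland-Altman bias and limits of agreement (radius-normalised)
#'
#' Agreement between estimated and reference radii, expressed relative to
#' the mean reference radius: the bias is the mean of the differences
#' (estimated minus reference) as a percentage of the mean reference, and
#' the limits of agreement are `1.96` sample standard deviations of the
#' differences, likewise as a percentage of the mean reference.
#'
#' @param estimated,reference Numeric vectors of equal length (mm); at
#'   least 2 pairs (the SD needs n - 1 degrees of freedom).
#' @return An object of class `lv_agreement` with fields `bias_percent`,
#'   `loa_percent`, `n`, `mean_reference_mm`, `sd_diff_mm`. Has
#'   [generics::tidy()] and [generics::glance()] methods.
#' @examples
#' bias_loa(estimated = c(12, 8), reference = c(10, 10))
#' @export
bias_loa <- function(estimated, reference) {
  if (!is.numeric(estimated) || !is.numeric(reference) ||
      length(estimated) != length(reference)) {
    stop("bias_loa: `estimated` and `reference` must be numeric vectors of equal length",
         call. = FALSE)
  }
  if (length(estimated) < 2L) {
    stop("bias_loa: at least 2 pairs are required for the limits of agreement",
         call. = FALSE)
  }
  diffs <- estimated - reference
  mref <- mean(reference)
  structure(
    list(bias_percent = mean(diffs) / mref * 100,
         loa_percent = 1.96 * stats::sd(diffs) / mref * 100,
         n = length(diffs),
         mean_reference_mm = mref,
         sd_diff_mm = stats::sd(diffs)),
    class = "lv_agreement"
  )
}

#' @export
print.lv_agreement <- function(x, ...) {
  cat(sprintf("<agreement: bias %+.2f%%, LOA %.2f%% (n = %d, mean reference %.2f mm)>\n",
              x$bias_percent, x$loa_percent, x$n, x$mean_reference_mm))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname bias_loa
#' @param x An `lv_agreement`.
#' @param ... Unused.
#' @export
tidy.lv_agreement <- function(x, ...) {
  tibble::tibble(
    term = c("bias_percent", "loa_percent"),
    estimate = c(x$bias_percent, x$loa_percent)
  )
}

#' @rdname bias_loa
#' @export
glance.lv_agreement <- function(x, ...) {
  tibble::tibble(bias_percent = x$bias_percent, loa_percent = x$loa_percent,
                 n = x$n, mean_reference_mm = x$mean_reference_mm,
                 sd_diff_mm = x$sd_diff_mm)
}

#' Published bench agreement statistics (reference constants)
#'
#' Bias and limits-of-agreement values reported by the original bench
#' validation of the three calculation methods, kept here as documented
#' reference constants. They are *not* reproducible from this package: the
#' raw measured conductances behind them were never published, so these
#' numbers characterise the physical bench experiments, not this
#' implementation. They are useful as orientation for the expected sign and
#' order of magnitude (e.g. the classical method overestimates radius by
#' tens of percent when the surround conducts).
#'
#' @return A tibble with columns `setting`, `acm`, `bias_percent`,
#'   `loa_percent` (`NA` where the source reports none).
#' @export
reference_agreement <- function() {
  tibble::tribble(
    ~setting,              ~acm,    ~bias_percent, ~loa_percent,
    "glass_sigma1",        "wei",   41.35,         48.05,
    "glass_sigma2",        "wei",   42.43,         47.22,
    "glass",               "lead",  -1.66,         16.33,
    "glass",               "lead",  -2.48,         16.33,
    "glass_sigma1",        "plate", -23.92,        40.01,
    "glass_sigma2",        "plate", -24.39,        39.90,
    "phantom_conductive",  "wei",   141.51,        13.75,
    "phantom_conductive",  "plate", 13.58,         26.03,
    "phantom_conductive",  "lead",  17.1,          26.72,
    "phantom_insulating",  "wei",   75.95,         12.93,
    "phantom_insulating",  "plate", 34.14,         NA,
    "phantom_insulating",  "lead",  -20.41,        NA
  )
}
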