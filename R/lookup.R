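# Lookup-table inversion: the forward models G(R) have no closed-form
# inverse, so R(G) is represented by a densely sampled, strictly monotone
# table with monotone piecewise-cubic interpolation between the knots.

#' Build a radius-to-conductance lookup table
#'
#' Samples the total conductance of one analytical calculation method on a
#' uniform radius grid and verifies that the sampled map is strictly
#' increasing (a prerequisite for inversion). For the plate method the model
#' is only physically faithful below the measurement spacing `L`; the
#' `plate_policy` controls what happens when the grid extends beyond it:
#' `"warn"` (default) keeps the full grid and records a validity note,
#' `"truncate"` cuts the grid at `L`, `"error"` refuses to build.
#'
#' @param acm One of `"wei"`, `"plate"`, `"lead"`.
#' @param cfg An [electrode_config()].
#' @param tissue An [tissue_model()].
#' @param R_min_mm,R_max_mm Grid bounds (mm); defaults `r0 + 0.5` to 80 mm,
#'   covering severely dilated ventricles.
#' @param n Grid size (default 2000, minimum 2).
#' @param plate_policy Validity policy for plate grids beyond `L`.
#'
#' @return An object of class `lv_lookup`: a tibble with columns
#'   `radius_mm`, `conductance_S`, carrying the build configuration as
#'   attributes.
#' @examples
#' tab <- build_lookup_table("wei", electrode_config(), tissue_model(0.7),
#'                           n = 200)
#' tab
#' @export
build_lookup_table <- function(acm = c("wei", "plate", "lead"), cfg, tissue,
                               R_min_mm = cfg$r0_mm + 0.5, R_max_mm = 80,
                               n = 2000,
                               plate_policy = c("warn", "truncate", "error")) {
  acm <- match.arg(acm)
  .assert_cfg(cfg); .assert_tissue(tissue)
  plate_policy <- match.arg(plate_policy)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 2)
  if (!(cfg$r0_mm < R_min_mm && R_min_mm < R_max_mm)) {
    stop("build_lookup_table: requires r0 < R_min_mm < R_max_mm", call. = FALSE)
  }
  note <- character(0)
  if (acm == "plate" && R_max_mm > cfg$L_mm) {
    msg <- sprintf("plate model applied beyond its validity range: grid extends past L = %g mm",
                   cfg$L_mm)
    if (plate_policy == "error") stop("build_lookup_table: ", msg, call. = FALSE)
    if (plate_policy == "truncate") {
      R_max_mm <- cfg$L_mm
      if (R_min_mm >= R_max_mm) {
        stop("build_lookup_table: truncation at L leaves an empty plate grid",
             call. = FALSE)
      }
    } else {
      note <- msg
      warning("build_lookup_table: ", msg, call. = FALSE)
    }
  }
  gfun <- function(R) acm_total_conductance(R, cfg, tissue, acm)
  new_lookup_table(gfun, acm, cfg, tissue, R_min_mm, R_max_mm, n, note)
}

# Core builder over an arbitrary G(R) sampler; split out so the strict
# monotonicity gate can be exercised with a non-monotone map.
new_lookup_table <- function(gfun, acm, cfg, tissue, R_min_mm, R_max_mm, n,
                             note = character(0)) {
  radii <- seq(R_min_mm, R_max_mm, length.out = n)
  G <- gfun(radii)
  if (any(!is.finite(G))) {
    stop("lookup table: non-finite conductance in the sampled map", call. = FALSE)
  }
  bad <- which(diff(G) <= 0)
  if (length(bad)) {
    stop(sprintf("lookup table: sampled conductance is not strictly increasing on [%.4g, %.4g] mm",
                 radii[bad[1]], radii[bad[1] + 1L]), call. = FALSE)
  }
  structure(
    tibble::tibble(radius_mm = radii, conductance_S = G),
    acm = acm, cfg = cfg, tissue = tissue,
    grid = list(R_min_mm = R_min_mm, R_max_mm = R_max_mm, n = n),
    note = note,
    class = c("lv_lookup", class(tibble::tibble()))
  )
}

#' @export
print.lv_lookup <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<lookup table: %s ACM, %d knots on [%g, %g] mm, G in [%.4g, %.4g] S>\n",
              attr(x, "acm"), g$n, g$R_min_mm, g$R_max_mm,
              x$conductance_S[1], x$conductance_S[nrow(x)]))
  if (length(attr(x, "note"))) cat("  note:", attr(x, "note"), "\n")
  NextMethod()
}

.assert_lookup <- function(table) {
  if (!inherits(table, "lv_lookup")) {
    stop("expected an `lv_lookup` (see build_lookup_table())", call. = FALSE)
  }
  invisible(table)
}

#' Invert measured conductance to cavity radius
#'
#' Monotone piecewise-cubic (Fritsch-Carlson) interpolation of the inverse
#' map `R(G)` through the table knots; knot conductances map back to their
#' radii exactly. Conductances outside the table span are clamped to the
#' nearest endpoint radius and flagged `in_range = FALSE` (noisy
#' measurements may fall marginally outside a valid table).
#'
#' @param G_S Measured conductances (S); vectorised, must be finite.
#' @param table An `lv_lookup` from [build_lookup_table()].
#'
#' @return A tibble with columns `conductance_S`, `radius_mm`, `acm`,
#'   `in_range`.
#' @examples
#' tab <- build_lookup_table("wei", electrode_config(), tissue_model(0.7),
#'                           n = 500)
#' G <- wei_conductance(25, electrode_config(), 0.7)
#' radius_from_conductance(G, tab)
#' @export
radius_from_conductance <- function(G_S, table) {
  .assert_lookup(table)
  if (length(G_S) == 0L) {
    return(tibble::tibble(conductance_S = numeric(0), radius_mm = numeric(0),
                          acm = character(0), in_range = logical(0)))
  }
  if (any(!is.finite(G_S))) {
    stop("radius_from_conductance: conductances must be finite", call. = FALSE)
  }
  inv <- stats::splinefun(table$conductance_S, table$radius_mm,
                          method = "monoH.FC")
  lo <- table$conductance_S[1]
  hi <- table$conductance_S[nrow(table)]
  in_range <- G_S >= lo & G_S <= hi
  R <- inv(pmin(pmax(G_S, lo), hi))
  R <- pmin(pmax(R, table$radius_mm[1]), table$radius_mm[nrow(table)])
  tibble::tibble(conductance_S = G_S, radius_mm = R,
                 acm = attr(table, "acm"), in_range = in_range)
}

#' Estimate radii (and optionally volumes) for a measurement table
#'
#' Data-frame-first wrapper around [radius_from_conductance()]: takes any
#' data frame with a conductance column, appends the estimated radius and
#' range flag, and optionally a volume from one of the volume models.
#'
#' @param data A data frame with a conductance column.
#' @param table An `lv_lookup`.
#' @param conductance_col Name of the conductance column (default
#'   `"conductance_S"`).
#' @param volume_model `NULL` (no volume), `"wyatt"` or `"cylinder"`.
#' @param length_mm Ventricle height / segment length for the volume model
#'   (mm).
#'
#' @return The input data as a tibble with columns `radius_mm`, `in_range`
#'   (and `volume_mL` if a volume model is chosen) appended.
#' @examples
#' cfg <- electrode_config()
#' tab <- build_lookup_table("wei", cfg, tissue_model(0.7), n = 500)
#' meas <- tibble::tibble(conductance_S = wei_conductance(c(15, 25), cfg, 0.7))
#' estimate_radius(meas, tab, volume_model = "wyatt", length_mm = 80)
#' @export
estimate_radius <- function(data, table, conductance_col = "conductance_S",
                            volume_model = NULL, length_mm = NULL) {
  stopifnot(is.data.frame(data))
  if (!conductance_col %in% names(data)) {
    stop(sprintf("estimate_radius: no column `%s` in `data`", conductance_col),
         call. = FALSE)
  }
  est <- radius_from_conductance(data[[conductance_col]], table)
  out <- dplyr::mutate(tibble::as_tibble(data),
                       radius_mm = est$radius_mm, in_range = est$in_range)
  if (!is.null(volume_model)) {
    volume_model <- match.arg(volume_model, c("wyatt", "cylinder"))
    if (is.null(length_mm)) {
      stop("estimate_radius: `length_mm` is required with a volume model",
           call. = FALSE)
    }
    out$volume_mL <- switch(volume_model,
                            wyatt = wyatt_volume(out$radius_mm, length_mm),
                            cylinder = cylinder_volume(out$radius_mm, length_mm))
  }
  out
}

#' Write / read a lookup table as annotated CSV
#'
#' Serialises an `lv_lookup` to a plain CSV (`radius_mm`, `conductance_S`)
#' preceded by `#`-prefixed metadata lines recording the method, geometry,
#' tissue model and grid, at full double precision so the table round-trips
#' exactly.
#'
#' @param table An `lv_lookup`.
#' @param path File path.
#' @return `write_lookup_csv()` returns `path` invisibly;
#'   `read_lookup_csv()` returns the reconstructed `lv_lookup`.
#' @export
write_lookup_csv <- function(table, path) {
  .assert_lookup(table)
  cfg <- attr(table, "cfg"); tis <- attr(table, "tissue")
  g <- attr(table, "grid")
  num <- function(x) format(x, digits = 17)
  meta <- c(
    sprintf("# lvcond lookup table"),
    sprintf("# acm: %s", attr(table, "acm")),
    sprintf("# r0_mm: %s", num(cfg$r0_mm)),
    sprintf("# d_mm: %s", num(cfg$d_mm)),
    sprintf("# L_mm: %s", num(cfg$L_mm)),
    sprintf("# sigma_blood_S_per_m: %s", num(tis$sigma_blood_S_per_m)),
    sprintf("# sigma_muscle_S_per_m: %s", num(tis$sigma_muscle_S_per_m)),
    sprintf("# sigma_background_S_per_m: %s", num(tis$sigma_background_S_per_m)),
    sprintf("# wall_thickness_mm: %s", num(tis$wall_thickness_mm)),
    sprintf("# background_outer_radius_mm: %s", num(tis$background_outer_radius_mm)),
    sprintf("# R_min_mm: %s", num(g$R_min_mm)),
    sprintf("# R_max_mm: %s", num(g$R_max_mm)),
    sprintf("# n: %d", g$n),
    if (length(attr(table, "note"))) sprintf("# note: %s", attr(table, "note"))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines("radius_mm,conductance_S", con)
  writeLines(paste(num(table$radius_mm), num(table$conductance_S), sep = ","),
             con)
  invisible(path)
}

#' @rdname write_lookup_csv
#' @export
read_lookup_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(meta_lines, regexec("^# ([A-Za-z0-9_]+): (.*)$", meta_lines))
  kv <- kv[lengths(kv) == 3L]
  meta <- stats::setNames(vapply(kv, `[`, "", 3L), vapply(kv, `[`, "", 2L))
  need <- c("acm", "r0_mm", "d_mm", "L_mm", "sigma_blood_S_per_m",
            "sigma_muscle_S_per_m", "sigma_background_S_per_m",
            "wall_thickness_mm", "background_outer_radius_mm",
            "R_min_mm", "R_max_mm", "n")
  if (!all(need %in% names(meta))) {
    stop("read_lookup_csv: missing metadata header lines", call. = FALSE)
  }
  body <- utils::read.csv(text = lines[!grepl("^#", lines)])
  cfg <- electrode_config(as.numeric(meta["r0_mm"]), as.numeric(meta["d_mm"]),
                          as.numeric(meta["L_mm"]))
  tis <- tissue_model(as.numeric(meta["sigma_blood_S_per_m"]),
                      as.numeric(meta["sigma_muscle_S_per_m"]),
                      as.numeric(meta["sigma_background_S_per_m"]),
                      as.numeric(meta["wall_thickness_mm"]),
                      as.numeric(meta["background_outer_radius_mm"]))
  structure(
    tibble::tibble(radius_mm = body$radius_mm,
                   conductance_S = body$conductance_S),
    acm = unname(meta["acm"]), cfg = cfg, tissue = tis,
    grid = list(R_min_mm = as.numeric(meta["R_min_mm"]),
                R_max_mm = as.numeric(meta["R_max_mm"]),
                n = as.integer(meta["n"])),
    note = if ("note" %in% names(meta)) unname(meta["note"]) else character(0),
    class = c("lv_lookup", class(tibble::tibble()))
  )
}
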