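#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a lookup table's conductance-radius curve
#'
#' @param object An `lv_lookup`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lv_lookup <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$radius_mm, y = .data$conductance_S)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::labs(
      x = "cavity radius (mm)", y = "total conductance (S)",
      title = sprintf("%s ACM characteristic", attr(object, "acm"))
    ) +
    ggplot2::theme_minimal()
}

#' Compare the conductance characteristics of the three methods
#'
#' Evaluates `G(R)` for each requested analytical calculation method over a
#' radius range under one geometry and tissue model, mirroring the standard
#' characteristic-curve comparison figure.
#'
#' @param cfg An [electrode_config()].
#' @param tissue An [tissue_model()].
#' @param acms Methods to include.
#' @param R_range_mm Radius range (mm).
#' @param n Curve resolution.
#' @return A ggplot.
#' @examples
#' plot_conductance_curves(electrode_config(), tissue_model(0.7))
#' @export
plot_conductance_curves <- function(cfg, tissue,
                                    acms = c("wei", "plate", "lead"),
                                    R_range_mm = c(cfg$r0_mm + 0.5, 50),
                                    n = 200) {
  .assert_cfg(cfg); .assert_tissue(tissue)
  R <- seq(R_range_mm[1], R_range_mm[2], length.out = n)
  curves <- purrr::map_dfr(acms, function(a)
    acm_conductance(R, cfg, tissue, acm = a))
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$R_mm, y = .data$G_total_S,
                               colour = .data$acm)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "cavity radius (mm)", y = "total conductance (S)",
                  colour = "method") +
    ggplot2::theme_minimal()
}

#' @rdname run_validation
#' @param object An `lv_validation`.
#' @export
autoplot.lv_validation <- function(object, ...) {
  ggplot2::ggplot(object$per_fixture,
                  ggplot2::aes(x = .data$true_radius_mm,
                               y = .data$mean_radius_mm)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_radius_mm - .data$sd_radius_mm,
                   ymax = .data$mean_radius_mm + .data$sd_radius_mm),
      colour = "#d95f02"
    ) +
    ggplot2::labs(
      x = "reference radius (mm)", y = "estimated radius (mm)",
      title = sprintf("generated: %s, inverted: %s (bias %+.2f%%, LOA %.2f%%)",
                      object$generate_acm, object$invert_acm,
                      object$agreement$bias_percent,
                      object$agreement$loa_percent)
    ) +
    ggplot2::theme_minimal()
}
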