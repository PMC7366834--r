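#' Plot delta-B against illumination difference
#'
#' Scatter of pairwise changes in dissimilarity against the illumination
#' difference of the pair, with the fitted regression line and its 95%
#' pointwise confidence band.
#'
#' @param records Plot-level pair records from [delta_dissimilarity()].
#' @param reg Optional prefitted [regress_delta_on_light()] result.
#' @return A ggplot object.
#' @export
plot_light_regression <- function(records, reg = NULL) {
  reg <- reg %||% regress_delta_on_light(records)
  band <- confidence_band(reg)
  dat <- records[records$group == "different_treatment", , drop = FALSE]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$light_diff, y = .data$delta_B)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = .data$light_diff, ymin = .data$lwr, ymax = .data$upr),
      inherit.aes = FALSE, fill = "grey70", alpha = 0.6
    ) +
    ggplot2::geom_line(
      data = band, ggplot2::aes(x = .data$light_diff, y = .data$fit),
      inherit.aes = FALSE, linewidth = 0.8
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = expression("Illumination difference (mol" ~ m^-2 ~ d^-1 * ")"),
      y = expression(Delta * "B (change in Bray-Curtis dissimilarity)")
    ) +
    ggplot2::theme_minimal()
}

#' Plot mean delta-B per group
#'
#' Group means of the change in dissimilarity with standard-error bars,
#' against the zero-change reference line.
#'
#' @param records Pair records from [delta_dissimilarity()] (plot level,
#'   subplot level, or both bound together).
#' @return A ggplot object.
#' @export
plot_delta_b_groups <- function(records) {
  sm <- summarise(group_by(records, .data$group),
                  mean_delta = mean(.data$delta_B),
                  se = sd(.data$delta_B) / sqrt(dplyr::n()),
                  .groups = "drop")
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$group, y = .data$mean_delta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_delta - .data$se,
      ymax = .data$mean_delta + .data$se
    )) +
    ggplot2::labs(x = NULL, y = expression("Mean" ~ Delta * "B")) +
    ggplot2::theme_minimal()
}

#' Plot per-treatment delta-pcf bands
#'
#' Mean change in relative neighbourhood density across replicates by
#' distance, with the configured confidence band, one panel per treatment.
#' Sustained excursions of the whole band below (above) zero at small
#' distances are the competition (facilitation) signature.
#'
#' @param summary Output of [delta_pcf_summary()].
#' @return A ggplot object.
#' @export
plot_delta_pcf <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      fill = "grey70", alpha = 0.7
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_delta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~treatment) +
    ggplot2::labs(x = "r (m)", y = expression(Delta * "pcf(r)")) +
    ggplot2::theme_minimal()
}
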