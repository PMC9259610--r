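#' Dual-isotope source map
#'
#' Plots reduction-corrected measurements in the (delta-18O, SP) plane on
#' the N2O/H2O scale, with the three endmember literature ranges drawn as
#' boxes and the N2O-reduction trajectory (slope `sp_epsilon /
#' d18O_epsilon`, 0.24 with the default fractionation constants) anchored
#' at the bacterial denitrification endmember.
#'
#' @param data Measurement table with `sp`, `d18O` and `group` columns
#'   (see [add_isotopocules()]).
#' @param endmembers An [endmember_set()].
#' @param red A [reduction_params()].
#' @param h2o_d18O Ambient-water delta-18O, per mil.
#' @return A ggplot object.
#' @export
plot_isotope_map <- function(data, endmembers = endmember_set(),
                             red = reduction_params(), h2o_d18O = 0.91) {
  check_df_cols(data, c("sp", "d18O", "group"))
  ci <- reduction_correct(data$sp, data$d18O, red, h2o_d18O)
  pts <- bind_cols(as_tibble(data["group"]), ci)
  slope <- red$sp_epsilon / red$d18O_epsilon
  bd <- filter(endmembers, .data$source == "BD")
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = endmembers,
      ggplot2::aes(
        xmin = .data$d18O_lo, xmax = .data$d18O_hi,
        ymin = .data$sp_lo, ymax = .data$sp_hi, fill = .data$source
      ),
      alpha = 0.25
    ) +
    ggplot2::geom_abline(
      intercept = bd$sp_mean - slope * bd$d18O_mean, slope = slope,
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$d18O_nr, y = .data$sp_nr, colour = .data$group)
    ) +
    ggplot2::labs(
      x = expression(delta^18 * O ~ "(N"[2] * "O/H"[2] * "O), ‰"),
      y = "Site preference, ‰",
      fill = "Endmember", colour = "Group"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Stacked source-fraction plot
#'
#' Per-sample stacked bars of the point-estimate source fractions from a
#' Monte Carlo partition.
#'
#' @param object An `n2o_partition` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.n2o_partition <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$sample_id, y = .data$estimate, fill = .data$source
    )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Fraction of N2O production", fill = "Source") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Ordination plot
#'
#' First two principal coordinates with axis variance in the labels.
#'
#' @param object A `pcoa_result`.
#' @param groups Optional group label per sample.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcoa_result <- function(object, groups = NULL, ...) {
  pts <- object$points
  if (!is.null(groups)) pts$group <- groups
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$axis1, y = .data$axis2)) +
    ggplot2::labs(
      x = sprintf("PCoA 1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PCoA 2 (%.1f%%)", 100 * object$explained[2])
    ) +
    ggplot2::theme_minimal()
  if (is.null(groups)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  }
}

#' C-D ratio by group
#'
#' Boxplot of per-cell C-D/(C-D+C-H) ratios across habitat groups.
#'
#' @param data Output of [process_spectra()].
#' @return A ggplot object.
#' @export
plot_cd_ratio <- function(data) {
  check_df_cols(data, c("group", "cd_ratio"))
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data$group, y = .data$cd_ratio, fill = .data$group
  )) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "(C-D)/(C-D + C-H)") +
    ggplot2::theme_minimal()
}
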