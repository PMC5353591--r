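#' Plot a cumulative DVH curve
#'
#' Step plot of cumulative relative volume against dose; curves from
#' several masks (e.g. anatomical vs Q- vs V-functional) can be stacked
#' with [dplyr::bind_rows()] and are colored by `mask_label`.
#'
#' @param object an `fl_dvh` tibble from [cumulative_dvh()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot fl_dvh
#' @export
autoplot.fl_dvh <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dose_gy, y = .data$volume_pct,
                                       color = .data$mask_label)) +
    ggplot2::geom_step(direction = "hv", linewidth = 0.6) +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume receiving \u2265 dose (%)",
                  color = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}

#' Plot stratified correlation strengths by metric family
#'
#' Bar chart of |r| for each metric, faceted by stratum, colored by
#' family (CT anatomical, Q perfusion, V ventilation) -- the graphical
#' twin of the stratified correlation table.
#'
#' @param object an `fl_subgroup_table` from [subgroup_correlations()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot fl_subgroup_table
#' @export
autoplot.fl_subgroup_table <- function(object, ...) {
  df <- dplyr::filter(object, .data$computable)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = abs(.data$r),
                                   fill = .data$family)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~subgroup) +
    ggplot2::labs(x = NULL, y = "|Spearman r| with RILT event", fill = "Family") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
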