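#' Plot regional hotspot load across a cohort
#'
#' Boxplots of the summed left+right semiquantitative load (0-6) per brain
#' region, optionally split by group (e.g. SVD type), mirroring the usual way
#' regional hotspot distribution is reported.
#'
#' @param loads A tibble binding [regional_load()] rows across patients, with
#'   an `id` column and optionally the grouping column.
#' @param group Optional column name to colour by.
#' @return A ggplot object.
#' @export
plot_regional_load <- function(loads, group = NULL) {
  loads$region <- factor(loads$region, levels = atlas_regions()$region)
  mapping <- if (is.null(group)) {
    ggplot2::aes(x = .data$region, y = .data$load_total)
  } else {
    ggplot2::aes(x = .data$region, y = .data$load_total,
                 fill = .data[[group]])
  }
  ggplot2::ggplot(loads, mapping) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::scale_y_continuous(limits = c(0, 6), breaks = 0:6) +
    ggplot2::labs(x = NULL, y = "hotspot load (left + right, 0-6)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
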