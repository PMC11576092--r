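#' Plot a metabolite time course
#'
#' Geometric mean concentration over minutes since the meal with a
#' compatibility-interval ribbon, optionally on a log concentration axis.
#' Requires ggplot2 (Suggests).
#'
#' @param records LOD-imputed long-format record tibble.
#' @param metabolite Metabolite id to plot.
#' @param level Coverage level for the ribbon; default 0.95.
#' @param log_y Log-scale the concentration axis.
#' @return A ggplot object.
#' @export
plot_timecourse <- function(records, metabolite, level = 0.95, log_y = FALSE) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_timecourse() requires ggplot2", call. = FALSE)
  }
  tab <- concentration_table(
    records[records$metabolite == metabolite, ],
    level = level
  )
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$minutes, y = .data$gmean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$gci_lower, ymax = .data$gci_upper),
      fill = "grey80"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "Minutes since meal completion",
      y = "Geometric mean concentration",
      title = metabolite
    ) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}
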