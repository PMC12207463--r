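## ggplot2 views of the result tables.

#' Plot per-group in-group choice ratios over training bins
#'
#' @param bias_table a `gs_bias_table` from [evaluate_group_bias()].
#' @return a ggplot.
#' @export
plot_bias_timecourse <- function(bias_table) {
  df <- bias_table |>
    dplyr::filter(!is.na(.data$ratio)) |>
    dplyr::group_by(.data$group, .data$bin) |>
    dplyr::summarise(mean_ratio = mean(.data$ratio), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$mean_ratio,
                                   colour = .data$group)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(red = "#960000", blue = "#000096")) +
    ggplot2::labs(x = "training bin", y = "in-group choice ratio",
                  title = "Dual-choice probe: in-group preference over training") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot group bias per bin for several conditions
#'
#' @param fig_table output of [reproduce_figure_table()] for `fig2c`-style
#'   panels (columns `condition`, `bin`, `bias`).
#' @return a ggplot.
#' @export
plot_ratio_sweep <- function(fig_table) {
  ggplot2::ggplot(fig_table, ggplot2::aes(x = .data$bin, y = .data$bias,
                                          colour = .data$condition)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "training bin", y = "group bias",
                  colour = "majority:minority",
                  title = "Group bias by mixed-server ratio") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gs_bias_table <- function(object, ...) plot_bias_timecourse(object)

#' Autoplot generic (re-exported to avoid a ggplot2 attach requirement)
#' @param object object to plot.
#' @param ... passed on.
#' @export
autoplot <- function(object, ...) UseMethod("autoplot")

#' @export
autoplot.gs_run <- function(object, ...) {
  if (is.null(object$bias)) abort("run has no probe results to plot")
  plot_bias_timecourse(object$bias)
}
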