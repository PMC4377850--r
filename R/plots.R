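#' Plot library composition
#'
#' Stacked per-library class percentages from a [composition_table()].
#'
#' @param composition tibble from [composition_table()].
#' @return a ggplot object.
#' @export
plot_composition <- function(composition) {
  df <- filter(composition, .data$class != "Raw reads")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$library,
                                   y = .data$total_percent,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "library", y = "% of raw reads", fill = "class") +
    ggplot2::theme_minimal()
}

#' Degradome t-plot
#'
#' Per-position tag abundance along a transcript with the expected
#' cleavage site highlighted.
#'
#' @param tplot a `chillmir_tplot` from [build_tplot()].
#' @param units "tpb" (default) or "count".
#' @return a ggplot object.
#' @export
plot_tplot <- function(tplot, units = c("tpb", "count")) {
  units <- match.arg(units)
  df <- tplot$abundance
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                        y = .data[[units]])) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, yend = 0)) +
    ggplot2::labs(x = "transcript position",
                  y = if (units == "tpb") "tags per billion" else "raw tags",
                  title = tplot$transcript_id) +
    ggplot2::theme_minimal()
  if (!is.na(tplot$expected_site)) {
    p <- p + ggplot2::geom_vline(xintercept = tplot$expected_site,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' @export
autoplot.chillmir_tplot <- function(object, ...) plot_tplot(object, ...)

#' Volcano-style view of two-library differential expression
#'
#' log2(CT/NT) against -log10 of the chi-square p-value, with the dual
#' thresholds drawn and significant features highlighted.
#'
#' @param object a `chillmir_de` from [diff_expression()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.chillmir_de <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  lfc <- attr(object, "lfc") %||% 1
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$log2_ratio,
                               y = -log10(.data$p_chisq),
                               colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = c(-lfc, lfc), linetype = "dotted") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dotted") +
    ggplot2::labs(x = "log2(CT/NT)", y = "-log10 p (chi-square)") +
    ggplot2::theme_minimal()
}

#' qPCR fold changes over time by condition
#'
#' @param object a `chillmir_qpcr` from [ddct_fold_change()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.chillmir_qpcr <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time_h, y = .data$fold_change,
                               colour = .data$condition,
                               group = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~gene) +
    ggplot2::labs(x = "time after treatment (h)",
                  y = "relative expression (2^-ddCt)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
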