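#' Plot coverage probabilities against the tolerable range
#'
#' One line per interval method, coverage against sample size, faceted by
#' predictor distribution and effect type, with the tolerable band
#' (0.935–0.965) shaded and the nominal 0.95 marked.
#'
#' @param summary A [summarize_coverage()] table (or raw
#'   [run_condition()] rows, summarized on the fly).
#' @param lower,upper Tolerable-range bounds to draw.
#' @return A ggplot object.
#' @export
plot_coverage <- function(summary, lower = 0.935, upper = 0.965) {
  if (!inherits(summary, "coverage_summary")) {
    summary <- summarize_coverage(summary)
  }
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$n, y = .data$coverage,
                               colour = .data$method)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = lower, ymax = upper,
                      alpha = 0.15, fill = "grey40") +
    ggplot2::geom_hline(yintercept = 0.95, linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$distribution),
      cols = ggplot2::vars(.data$effect_type)
    ) +
    ggplot2::labs(x = "sample size", y = "coverage probability",
                  colour = "method") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.coverage_summary <- function(object, ...) plot_coverage(object, ...)

#' @exportS3Method ggplot2::autoplot
autoplot.coverage_result <- function(object, ...) plot_coverage(object, ...)
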