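# Figures: Bland-Altman scatter with bias/limit lines, and per-group metric
# boxplots.

#' Bland-Altman plot
#'
#' Scatter of per-pair differences against per-pair means with horizontal
#' lines at the bias and the limits of agreement.
#'
#' @param ba A [bland_altman()] result.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(ba, title = NULL) {
  ggplot2::ggplot(ba$points, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = ba$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::labs(x = "Mean of paired measurements (cm)",
                  y = "Difference (cm)", title = title) +
    ggplot2::theme_minimal()
}

#' Per-metric boxplots by group
#'
#' Boxplots of per-reader peak metrics for each software/repetition group,
#' with the automated single-run value overlaid as a horizontal reference when
#' present.
#'
#' @param metrics A per-session metrics tibble from [study_metrics()].
#' @param metric_names Metrics to plot (default all seven).
#' @return A ggplot object, faceted by metric.
#' @export
plot_metric_boxplots <- function(metrics, metric_names = METRIC_LEVELS) {
  long <- metrics_long(metrics)
  long <- long[long$metric %in% metric_names, ]
  manual <- long[long$type == "manual", ]
  manual$group <- sprintf("%s T%d", manual$software, manual$repetition)
  p <- ggplot2::ggplot(manual, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  auto <- long[long$type == "automated", ]
  if (nrow(auto) > 0) {
    p <- p + ggplot2::geom_hline(data = auto,
                                 ggplot2::aes(yintercept = .data$value),
                                 linetype = "dotted", colour = "firebrick")
  }
  p
}
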