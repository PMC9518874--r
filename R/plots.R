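#' Histogram of rhythm p-values
#'
#' The standard sanity plot for a genome-wide rhythm scan: uniform with an
#' excess near zero when the detector fits the data.
#'
#' @param rhythm tibble with a `p_value` column.
#' @param bins number of bins.
#' @return A ggplot object.
#' @export
plot_pvalue_histogram <- function(rhythm, bins = 20) {
  ggplot2::ggplot(rhythm, ggplot2::aes(x = .data$p_value)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0, fill = "grey35",
                            colour = "white") +
    ggplot2::geom_hline(yintercept = sum(is.finite(rhythm$p_value)) / bins,
                        linetype = "dashed") +
    ggplot2::labs(x = "rhythm p-value", y = "genes") +
    ggplot2::theme_minimal()
}

#' Distribution of per-gene delta values
#'
#' @param deltas a [delta_expression()] result.
#' @return A ggplot object.
#' @export
plot_delta_distribution <- function(deltas) {
  ggplot2::ggplot(deltas, ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = expression(delta ~ "(rhythmic - non-rhythmic tissues)"),
                  y = "genes") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fstar_fit <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = log(.data$mu),
                                       y = log(.data$fstar))) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.5) +
    ggplot2::labs(x = "log mean expression", y = "log F*",
                  subtitle = sprintf("polynomial degree %d",
                                     object$degree_selected[1])) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rhythm_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(unclass(object)),
                              c("mean_rhythmic", "mean_other"),
                              names_to = "group", values_to = "mean")
  long$group <- ifelse(long$group == "mean_rhythmic", "rhythmic", "other")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$category, y = .data$mean,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "group mean (analysis scale)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom broom tidy
#' @export
broom::tidy

#' @importFrom broom glance
#' @export
broom::glance
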