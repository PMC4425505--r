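#' Bar plot of splice-variant relative frequencies by group
#'
#' Grouped bars of the per-group mean relative frequency per variant, with
#' mean +/- SD error bars.
#'
#' @param object A `splice_frequency_table` from [summarize_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.splice_frequency_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$variant, y = .data$mean,
                               fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7, colour = "black") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "relative frequency", fill = NULL) +
    ggplot2::theme_classic()
}

#' Histogram of HA/gephyrin congruency ratios
#'
#' @param object A `congruency_result` from [congruency_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.congruency_result <- function(object, ...) {
  h <- object$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_lower + object$bin_width / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = object$bin_width * 0.95, fill = "grey35") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "HA / gephyrin intensity ratio", y = "clusters",
                  subtitle = sprintf("n = %d, R = %.2f", object$n, object$R)) +
    ggplot2::theme_classic()
}

#' Bar plot of splice-site strength scores
#'
#' @param object A `site_ranking` from [rank_locus_sites()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.site_ranking <- function(object, ...) {
  d <- dplyr::arrange(object, .data$kind, .data$position)
  d$label <- factor(d$label, levels = d$label)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$score)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~kind, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "splicing strength (bits)") +
    ggplot2::theme_classic()
}
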