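# ggplot2 figure methods: DMPW frequency bars, pattern-profile bubbles,
# network degree panels, density boxplots and a forest plot for the
# multinomial fit.

#' @exportS3Method ggplot2::autoplot
autoplot.nutrinet_dmpw_table <- function(object, ...) {
  by_cols <- setdiff(names(object), c("dmpw", "n", "pct"))
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$dmpw, y = .data$pct,
                                    fill = .data$dmpw)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "% of subjects",
                  title = "Divergence between measured and perceived weight") +
    ggplot2::theme_minimal()
  if (length(by_cols) > 0) {
    p <- p + ggplot2::facet_wrap(stats::as.formula(
      paste("~", paste(by_cols, collapse = "+"))))
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.nutrinet_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = factor(.data$pattern), y = .data$group,
                               size = .data$mean, colour = .data$mean)) +
    ggplot2::geom_point() +
    ggplot2::scale_size_area(max_size = 10) +
    ggplot2::labs(x = "dietary pattern", y = NULL,
                  size = "mean abundance", colour = "mean abundance",
                  title = "Abundance of consumption per dietary pattern") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.nutrinet_network <- function(object, ...) {
  deg <- node_degrees(object)
  ggplot2::ggplot(deg,
                  ggplot2::aes(x = .data$degree,
                               y = stats::reorder(.data$group, .data$degree))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "number of retained correlations", y = NULL,
                  title = sprintf("Node analysis (L = %d, density = %.3f)",
                                  object$L, object$density)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.nutrinet_multifit <- function(object, ...) {
  d <- dplyr::filter(tidy(object), .data$term != "(Intercept)")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::labs(x = "odds ratio (95% CI)", y = NULL,
                  title = paste("Multinomial model, baseline pattern",
                                object$baseline)) +
    ggplot2::theme_minimal()
}

#' Boxplot of per-replicate bootstrap densities by group
#'
#' @param comparison A `"nutrinet_comparison"` from [compare_densities()].
#' @return A ggplot.
#' @export
plot_density_comparison <- function(comparison) {
  if (is.null(comparison$densities)) {
    abort("comparison carries no replicate densities")
  }
  ggplot2::ggplot(comparison$densities,
                  ggplot2::aes(x = .data$group, y = .data$density,
                               fill = .data$group)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "network density (per bootstrap replicate)",
                  title = sprintf("Kruskal-Wallis p = %s",
                                  format.pval(comparison$p_value))) +
    ggplot2::theme_minimal()
}
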