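#' Plot an additive count distribution
#'
#' Bar chart of the share of products carrying 0 to 10+ additives,
#' facetted by stratum when the distribution was computed with `by`.
#'
#' @param object An [ets_count_distribution()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ets_count_dist <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$n_ets, y = .data$share)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Number of additives per product",
                  y = "Share of products") +
    ggplot2::theme_minimal()
  extra <- setdiff(names(object), c("n_ets", "n", "share"))
  if (length(extra) > 0) {
    p <- p + ggplot2::facet_wrap(stats::as.formula(paste("~", extra[1])))
  }
  p
}

#' Plot a fold-enrichment scan
#'
#' Dot-and-interval chart of fold enrichment per combination and food
#' group (intervals are the bootstrap percentile bounds of log fold
#' enrichment, back-transformed); the dashed line marks the independence
#' expectation of 1.
#'
#' @param object An [enrichment_scan()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ets_enrichment <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold_enrichment,
                                   y = .data$combo)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = exp(.data$ci_lo), xmax = exp(.data$ci_hi)),
      height = 0.2, na.rm = TRUE
    ) +
    ggplot2::geom_point(ggplot2::aes(size = .data$observed / .data$n_group)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~group, scales = "free_y") +
    ggplot2::labs(x = "Fold enrichment (log scale)", y = NULL,
                  size = "Share of group") +
    ggplot2::theme_minimal()
}

#' Heatmap of per-group additive prevalence
#'
#' @param prevalence A [prevalence_table()] result.
#' @return A ggplot tile chart of prevalence (percent) by additive and
#'   food group.
#' @export
plot_prevalence_heatmap <- function(prevalence) {
  ggplot2::ggplot(prevalence,
                  ggplot2::aes(x = .data$code, y = .data$group,
                               fill = .data$prevalence_pct)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "% of products") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
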