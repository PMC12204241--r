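# ggplot2 helpers for the main result types. Each returns a ggplot object.

#' Plot permutation calibration
#'
#' Histogram of permutation p-values with the uniform reference line; a
#' calibrated pipeline is flat.
#'
#' @param x A `qb_calibration` from [permutation_calibration()].
#' @param bins Histogram bins.
#' @return A ggplot.
#' @export
plot_calibration <- function(x, bins = 20) {
  df <- tibble(p = x$p_values[is.finite(x$p_values)])
  ggplot2::ggplot(df, ggplot2::aes(x = p)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0, fill = "grey55") +
    ggplot2::geom_hline(yintercept = nrow(df) / bins, linetype = 2) +
    ggplot2::labs(x = "permutation p-value", y = "count",
                  title = "Null calibration of the proportion model") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.qb_calibration <- function(object, ...) plot_calibration(object, ...)

#' Plot pooled effects from a meta-analysis table
#'
#' Dot plot of pooled log-odds slopes per (unit, trait), faceted by region,
#' with conserved associations highlighted.
#'
#' @param meta Tibble from [meta_analyze()].
#' @param response_col Unit column (default `"subcluster"`).
#' @return A ggplot.
#' @export
plot_meta_effects <- function(meta, response_col = "subcluster") {
  ggplot2::ggplot(meta, ggplot2::aes(
    x = trait, y = .data[[response_col]],
    size = -log10(pmax(p_adj, 1e-10)), color = conserved
  )) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~region) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey70",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(size = "-log10 FDR", color = "conserved") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot median silhouette across cut heights
#'
#' @param x A `donor_clustering` from [cluster_donors()].
#' @return A ggplot.
#' @export
plot_silhouette <- function(x) {
  ggplot2::ggplot(x$silhouette,
                  ggplot2::aes(x = k, y = median_silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = x$chosen_k, linetype = 2) +
    ggplot2::labs(x = "number of donor subgroups",
                  y = "median silhouette") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.donor_clustering <- function(object, ...) plot_silhouette(object)

#' Heatmap of normalized locus accessibility
#'
#' Tiles of max-normalized accessibility per locus across
#' (region, cell class, population group) combinations.
#'
#' @param values Tibble from [locus_values()].
#' @return A ggplot.
#' @export
plot_locus_accessibility <- function(values) {
  values$combo <- interaction(values$region, values$cell_class,
                              values$group, sep = " / ")
  ggplot2::ggplot(values, ggplot2::aes(x = combo, y = locus,
                                       fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "accessibility") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
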