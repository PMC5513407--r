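#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Plot a feature histogram
#'
#' Bar-chart view of a [feature_histogram()].
#'
#' @param object a `net_histogram`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.net_histogram <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$mid <- (df$bin_lo + df$bin_hi) / 2
  width <- if (nrow(df) > 1) df$bin_hi[1] - df$bin_lo[1] else 1
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = width * 0.95, fill = "grey30") +
    ggplot2::labs(x = "value", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot a feature correlation matrix
#'
#' Heat-map of the pairwise Pearson correlations from
#' [correlation_matrix()], the numerical part of the all-against-all
#' feature comparison.
#'
#' @param object a `net_corr`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.net_corr <- function(object, ...) {
  M <- unclass(object)
  df <- tidyr::expand_grid(x = rownames(M), y = colnames(M))
  df$r <- M[cbind(df$x, df$y)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac",
                                  mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal()
}

#' Compare profiles of several networks as a bar chart
#'
#' The side-by-side bar-chart view of an [inter_profile()] table: one panel
#' per metric, one bar per network.
#'
#' @param profiles tibble from [inter_profile()].
#' @param metrics character vector of numeric profile columns to show;
#'   defaults to the common centrality/clustering panel.
#' @return a ggplot object.
#' @export
plot_profile_comparison <- function(profiles,
                                    metrics = c("average_local_clustering", "density",
                                                "mean_closeness", "mean_betweenness",
                                                "mean_degree")) {
  metrics <- intersect(metrics, names(profiles))
  long <- tidyr::pivot_longer(profiles[, c("name", metrics)],
                              -"name", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$name, y = .data$value, fill = .data$name)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Degree-distribution histogram of a network
#'
#' Convenience wrapper: histogram of the node degrees.
#'
#' @param g a `netgraph`.
#' @param bins bin count or `"auto"` (Sturges).
#' @return a ggplot object.
#' @export
plot_degree_distribution <- function(g, bins = "auto") {
  autoplot(feature_histogram(node_degrees(g)$degree, bins)) +
    ggplot2::labs(x = "degree")
}
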