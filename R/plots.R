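#' Enrichment dot plot
#'
#' The standard pathway dot plot: gene ratio on the x axis, pathways on the
#' y axis ordered by gene ratio, dot size proportional to the number of
#' overlapping genes and colour encoding the adjusted p-value.
#'
#' @param object A `netgsea_gsea` result (or, for the ORA method, a
#'   `netgsea_ora` tibble).
#' @param top_n Number of top sets (by adjusted p) to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot netgsea_gsea
#' @export
autoplot.netgsea_gsea <- function(object, top_n = 20, ...) {
  dotplot_gg(dotplot_data(object), top_n)
}

#' @rdname autoplot.netgsea_gsea
#' @method autoplot netgsea_ora
#' @export
autoplot.netgsea_ora <- function(object, top_n = 20, ...) {
  dotplot_gg(dotplot_data(object), top_n)
}

dotplot_gg <- function(df, top_n) {
  df <- slice_head(arrange(df, .data$p_adj), n = top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$gene_ratio,
    y = stats::reorder(.data$set_name, .data$gene_ratio),
    size = .data$overlap_count, colour = .data$p_adj
  )) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "#b2182b", high = "#2166ac") +
    ggplot2::labs(x = "gene ratio", y = NULL,
                  size = "overlap", colour = "adjusted p") +
    ggplot2::theme_minimal()
}

#' Ranked centrality before and after the Hill transformation
#'
#' Plots the sorted betweenness centralities (solid) against their
#' Hill-transformed scores (dashed) by rank, showing how the sigmoid
#' suppresses the long tail of peripheral nodes while saturating hubs.
#'
#' @param centrality [network_centrality()] table.
#' @param h,k,q Hill parameters as in [rank_centrality()].
#' @return A ggplot object.
#' @export
plot_hill_curve <- function(centrality, h = 4, k = NULL, q = 0.90) {
  values <- sort(centrality$betweenness, decreasing = TRUE)
  if (is.null(k)) k <- choose_k(values, h = h, q = q)
  df <- bind_rows(
    tibble(rank = seq_along(values), value = values, series = "betweenness"),
    tibble(rank = seq_along(values),
           value = sort(hill_transform(values, h, k), decreasing = TRUE),
           series = "Hill-transformed")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$value,
                                   linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(betweenness = "solid",
                                              `Hill-transformed` = "dashed")) +
    ggplot2::labs(x = "node rank", y = "centrality / score",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}
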