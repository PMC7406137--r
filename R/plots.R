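#' Plot a trained SOM as a hexagonal node map
#'
#' @param object A `som_fit`.
#' @param fill Node statistic to colour by: `"n_genes"` (default) or a
#'   tibble `(node, value)` to map onto the grid.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot som_fit
#' @export
autoplot.som_fit <- function(object, fill = "n_genes", ...) {
  g <- object$grid
  if (is.data.frame(fill)) {
    g$value <- fill$value[match(g$unit, fill$node)]
    lab <- "value"
  } else {
    g$value <- tabulate(object$assignment$node, nbins = object$units)
    lab <- "genes"
  }
  ggplot(g, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_point(shape = 21, size = 9, colour = "grey30") +
    geom_text(aes(label = .data$unit), size = 2.5) +
    scale_fill_viridis_c(name = lab) +
    coord_equal() +
    theme_void() +
    labs(title = paste0(object$rows, " x ", object$cols, " hexagonal SOM"))
}

#' Heatmap of node-by-substrate expression or fold change
#'
#' @param stats Node summaries from [node_stats()].
#' @param value Column to display (`"mean_log2"` or `"log2_fc"`).
#' @return A ggplot.
#' @export
plot_node_stats <- function(stats, value = "mean_log2") {
  ggplot(stats, aes(x = .data$substrate, y = factor(.data$node),
                    fill = .data[[value]])) +
    geom_tile() +
    scale_fill_viridis_c(name = value) +
    labs(x = NULL, y = "node") +
    theme_minimal(base_size = 9)
}

#' Heatmap of the cross-species sample correlation matrix
#'
#' @param cor_tbl Long correlation tibble from [sample_correlation()].
#' @return A ggplot.
#' @export
plot_sample_correlation <- function(cor_tbl) {
  ggplot(cor_tbl, aes(x = .data$sample_a, y = .data$sample_b,
                      fill = .data$r)) +
    geom_tile() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                         limits = c(-1, 1)) +
    theme_minimal(base_size = 7) +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5)) +
    labs(x = NULL, y = NULL)
}

#' Heatmap of co-ortholog log2 fold changes
#'
#' @param fold_matrix Long fold-change tibble from
#'   [coortholog_fold_matrix()].
#' @return A ggplot.
#' @export
plot_fold_matrix <- function(fold_matrix) {
  ggplot(fold_matrix,
         aes(x = paste(.data$species, .data$substrate, sep = ":"),
             y = .data$group_id, fill = .data$log2_fc)) +
    geom_tile() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    theme_minimal(base_size = 7) +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5),
          axis.text.y = element_blank()) +
    labs(x = NULL, y = "orthogroup", fill = "log2 FC")
}
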