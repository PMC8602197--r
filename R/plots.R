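# ggplot2 views of the main result objects

#' Volcano plot of a differential-expression result
#'
#' @param object A `circ_de` tibble from [differential_expression()].
#' @param ... Unused.
#' @return A ggplot: `log2fc` vs `-log10(q)`, points colored by status,
#'   dashed lines at the fold-change and q-value gates.
#' @export
autoplot.circ_de <- function(object, ...) {
  th <- attr(object, "thresholds")
  pair <- attr(object, "pair")
  df <- tibble::as_tibble(object) %>%
    mutate(neglog_q = -log10(pmax(.data$q, .Machine$double.xmin)))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, .data$neglog_q,
                                   color = .data$status)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::geom_vline(xintercept = c(-th[["lfc_min"]], th[["lfc_min"]]),
                        linetype = "dashed", color = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(th[["q_max"]]),
                        linetype = "dashed", color = "grey40") +
    ggplot2::scale_color_manual(values = c(up = "#3366cc", down = "#cc3333",
                                           ns = "#66aa66")) +
    ggplot2::labs(x = "log2(fold change)", y = "-log10(q)",
                  title = sprintf("%s vs %s", pair[1], pair[2])) +
    ggplot2::theme_minimal()
}

#' Z-score heatmap of a clustering result
#'
#' @param object A `circ_cluster` from [zscore_cluster()].
#' @param ... Unused.
#' @return A ggplot tile heatmap, features ordered by the dendrogram and
#'   stripe-annotated by cluster.
#' @export
autoplot.circ_cluster <- function(object, ...) {
  ord <- object$feature_hclust$order
  feat <- rownames(object$z)[ord]
  cols <- if (!is.null(object$profile_hclust)) {
    colnames(object$z)[object$profile_hclust$order]
  } else colnames(object$z)
  df <- as.data.frame(object$z) %>%
    mutate(feature_id = rownames(object$z)) %>%
    tidyr::pivot_longer(-"feature_id", names_to = "profile",
                        values_to = "z") %>%
    left_join(object$assignments, by = "feature_id") %>%
    mutate(feature_id = factor(.data$feature_id, levels = feat),
           profile = factor(.data$profile, levels = cols))
  ggplot2::ggplot(df, ggplot2::aes(.data$profile, .data$feature_id,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(cluster ~ ., scales = "free_y", space = "free_y") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Z-score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Bar chart of circRNA classes
#'
#' @param annotations Tibble from [classify_junctions()].
#' @return A ggplot bar chart of exonic/intronic/intergenic counts.
#' @export
plot_circ_classes <- function(annotations) {
  df <- annotations %>% count(.data$circ_class)
  ggplot2::ggplot(df, ggplot2::aes(.data$circ_class, .data$n,
                                   fill = .data$circ_class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.3) +
    ggplot2::labs(x = NULL, y = "circRNAs") +
    ggplot2::theme_minimal()
}
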