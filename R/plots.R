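#' Volcano plot of a differential result
#'
#' @param diff Result tibble from [classify_features()].
#' @param label_thresholds Draw dashed guides at |log2FC| = 1 and p = 0.05.
#' @return A ggplot object.
#' @export
plot_volcano <- function(diff, label_thresholds = TRUE) {
  check_columns(diff, c("log2fc", "p", "class"), "diff")
  d <- diff[!is.na(diff$p), ]
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$log2fc, -log10(.data$p),
                                       colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(hit = "#c0392b",
                                            candidate = "#e67e22",
                                            none = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
  if (label_thresholds) {
    p <- p +
      ggplot2::geom_vline(xintercept = c(-1, 1), linetype = "dashed",
                          colour = "grey40") +
      ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed",
                          colour = "grey40")
  }
  p
}

#' Elbow curve of a cluster scan
#'
#' @param object A `cluster_result`.
#' @param ... Unused.
#' @return A ggplot of within-cluster sum of squares vs k, with the chosen
#'   k marked.
#' @method autoplot cluster_result
#' @export
autoplot.cluster_result <- function(object, ...) {
  ggplot2::ggplot(object$wss, ggplot2::aes(.data$k, .data$wss)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed",
                        colour = "#c0392b") +
    ggplot2::scale_x_continuous(breaks = object$wss$k) +
    ggplot2::labs(x = "number of clusters k",
                  y = "within-cluster sum of squares") +
    ggplot2::theme_minimal()
}

#' Heatmap of Spearman sample correlations
#'
#' @param object A `sample_clustering` object.
#' @param ... Unused.
#' @return A ggplot tile heatmap with samples in dendrogram leaf order.
#' @method autoplot sample_clustering
#' @export
autoplot.sample_clustering <- function(object, ...) {
  rho <- object$correlation[object$order, object$order]
  d <- tibble::tibble(
    sample_a = factor(rep(rownames(rho), times = ncol(rho)),
                      levels = object$order),
    sample_b = factor(rep(colnames(rho), each = nrow(rho)),
                      levels = object$order),
    rho = as.vector(rho)
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$sample_a, .data$sample_b,
                                  fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2c7bb6", mid = "white",
                                  high = "#d7191c", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Bar chart of phosphosite residue counts
#'
#' @param breakdown Tibble from [residue_breakdown()].
#' @return A ggplot bar chart.
#' @export
plot_residue_breakdown <- function(breakdown) {
  check_columns(breakdown, c("residue", "n"), "breakdown")
  ggplot2::ggplot(breakdown, ggplot2::aes(.data$residue, .data$n)) +
    ggplot2::geom_col(fill = "#2c7bb6") +
    ggplot2::labs(x = "phosphosite residue", y = "count") +
    ggplot2::theme_minimal()
}
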