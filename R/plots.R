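# ggplot2 visualisations for the main result types.

#' @export
autoplot.mst_graph <- function(object, ...) {
  v <- object$vertices
  e <- dplyr::mutate(object$edges,
                     row = v$row[.data$i], col = v$col[.data$i],
                     row_end = v$row[.data$j], col_end = v$col[.data$j])
  ggplot2::ggplot(v, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_segment(data = e,
                          ggplot2::aes(xend = .data$col_end,
                                       yend = .data$row_end),
                          colour = "grey40") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "col (px)", y = "row (px)",
                  title = sprintf("MST: %d vertices, total weight %.1f px",
                                  nrow(v), sum(object$edges$weight))) +
    ggplot2::theme_minimal()
}

#' Plot a clustered nucleus set
#'
#' Vertices coloured by cluster, retained intra-cluster MST edges solid,
#' removed (inconsistent) edges dashed red; optionally the inter-cluster
#' MST over the cluster centroids.
#'
#' @param object A `cluster_set`.
#' @param show_inter Overlay the inter-cluster MST (default TRUE when
#'   there is more than one cluster).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_set <- function(object, show_inter = NULL, ...) {
  v <- dplyr::mutate(object$vertices,
                     cluster = factor(object$membership))
  e <- dplyr::mutate(object$edges,
                     row = v$row[.data$i], col = v$col[.data$i],
                     row_end = v$row[.data$j], col_end = v$col[.data$j])
  if (is.null(show_inter)) show_inter <- length(object$clusters) > 1L
  p <- ggplot2::ggplot(v, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_segment(data = dplyr::filter(e, .data$kept),
                          ggplot2::aes(xend = .data$col_end,
                                       yend = .data$row_end),
                          colour = "grey40") +
    ggplot2::geom_segment(data = dplyr::filter(e, !.data$kept),
                          ggplot2::aes(xend = .data$col_end,
                                       yend = .data$row_end),
                          colour = "red", linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$cluster), size = 1.5)
  if (show_inter && length(object$clusters) > 1L) {
    im <- inter_cluster_mst(object)
    iv <- im$vertices
    ie <- dplyr::mutate(im$edges,
                        row = iv$row[.data$i], col = iv$col[.data$i],
                        row_end = iv$row[.data$j], col_end = iv$col[.data$j])
    p <- p +
      ggplot2::geom_segment(data = ie,
                            ggplot2::aes(xend = .data$col_end,
                                         yend = .data$row_end),
                            colour = "blue", linewidth = 0.7) +
      ggplot2::geom_point(data = iv, shape = 17, size = 2.5,
                          colour = "blue")
  }
  p + ggplot2::scale_y_reverse() + ggplot2::coord_equal() +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = "col (px)", y = "row (px)",
                  title = sprintf("%d nuclei in %d clusters",
                                  nrow(v), length(object$clusters))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.vote_matrix <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(object, feature = factor(.data$feature,
                                           levels = rev(.data$feature))),
    cols = dplyr::where(is.logical),
    names_to = "method", values_to = "vote")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$feature,
                                     fill = .data$vote)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8",
                                          `FALSE` = "grey85")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "selected",
                  title = sprintf("Majority voting (min votes = %s)",
                                  attr(object, "min_votes"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a metrics table
#'
#' Bar chart of the per-split metrics emitted by [five_fold_evaluate()].
#'
#' @param metrics Tibble from [five_fold_evaluate()].
#' @return A ggplot object.
#' @export
plot_metrics <- function(metrics) {
  long <- tidyr::pivot_longer(metrics,
                              cols = c("accuracy", "precision",
                                       "recall", "f1"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$split, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "percent") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
tidy.nc_rf <- function(x, ...) {
  tibble::tibble(feature = names(x$importance),
                 importance = as.numeric(x$importance))
}

#' @export
tidy.vote_matrix <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.vote_matrix <- function(x, ...) {
  tibble::tibble(n_features = nrow(x),
                 n_selected = length(attr(x, "selected")),
                 n_rejected = length(attr(x, "rejected")),
                 min_votes = attr(x, "min_votes"))
}
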