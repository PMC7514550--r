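#' Plot an RR tachogram
#'
#' @param object an [rr_series()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot rr_series
#' @export
autoplot.rr_series <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$t_s / 60, y = .data$rr_ms)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (min)", y = "RR (ms)",
                  title = sprintf("subject %s, age %s", rr_subject(object),
                                  rr_age(object))) +
    ggplot2::theme_minimal()
}

#' Heatmap of a cohort correlation matrix
#'
#' @param matrix a [correlation_matrix()].
#' @return a ggplot tile map in canonical feature order.
#' @export
plot_correlation_matrix <- function(matrix) {
  d <- tibble::as_tibble(matrix, rownames = "f1")
  d <- tidyr::pivot_longer(d, -"f1", names_to = "f2", values_to = "r")
  ord <- rownames(matrix)
  d$f1 <- factor(d$f1, levels = ord)
  d$f2 <- factor(d$f2, levels = rev(ord))
  ggplot2::ggplot(d, ggplot2::aes(.data$f1, .data$f2, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r")
}

#' Plot factor loadings
#'
#' @param object an `hrv_fa`.
#' @param ... unused.
#' @return a ggplot tile map of loadings, dominant cells outlined.
#' @method autoplot hrv_fa
#' @export
autoplot.hrv_fa <- function(object, ...) {
  d <- tidy(object)
  if (nrow(d) == 0) {
    rlang::abort("no retained factors to plot", class = "hrvdyn_validation_error")
  }
  d$feature <- factor(d$feature, levels = rev(object$features))
  ggplot2::ggplot(d, ggplot2::aes(.data$factor, .data$feature,
                                  fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = d[d$dominant, ], fill = NA, colour = "black",
                       linewidth = 0.4) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "loading")
}

#' Plot a posterior-probability matrix
#'
#' Rows are subjects ordered by their true decade, columns are decade
#' classes; the tile fill is the across-run mean posterior probability.
#'
#' @param object an `hrv_svm`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot hrv_svm
#' @export
autoplot.hrv_svm <- function(object, ...) {
  d <- tidy(object)
  ord <- order(d$truth[seq_len(object$n)])
  d$row <- factor(match(d$subject, ord), levels = seq_len(object$n))
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$class), .data$row,
                                  fill = .data$prob_mean)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank()) +
    ggplot2::labs(x = "decade class", y = "subjects (by true decade)",
                  fill = "posterior")
}

#' Plot a strong-correlation graph
#'
#' @param object an `hrv_corr_graph`.
#' @param ... unused.
#' @return a ggplot of nodes (circle layout) and edges, solid for positive
#'   and dashed for negative correlations.
#' @method autoplot hrv_corr_graph
#' @export
autoplot.hrv_corr_graph <- function(object, ...) {
  g <- object$graph
  lay <- igraph::layout_in_circle(g)
  nodes <- tibble::tibble(name = igraph::V(g)$name,
                          x = lay[, 1], y = lay[, 2])
  e <- object$edges
  e$x <- nodes$x[match(e$from, nodes$name)]
  e$y <- nodes$y[match(e$from, nodes$name)]
  e$xend <- nodes$x[match(e$to, nodes$name)]
  e$yend <- nodes$y[match(e$to, nodes$name)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = e,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linetype = .data$r < 0),
                          colour = "grey40", show.legend = FALSE) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x * 1.12, .data$y * 1.12,
                                    label = .data$name), size = 2.8) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("|r| >= %.2f", object$theta))
}
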