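#' Plot an MDS embedding
#'
#' Scatter of the 2-D document embedding, coloured by textbook and
#' shaped by disease when those labels are present. If `boundary` (the
#' result of [boundary_f1()]) is supplied, its zero-level decision
#' contour is overlaid.
#'
#' @param object An `mds_embedding`.
#' @param boundary Optional result of [boundary_f1()] on this embedding.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mds_embedding
#' @export
autoplot.mds_embedding <- function(object, boundary = NULL, ...) {
  df <- tibble::as_tibble(object)
  aes_args <- list(x = quote(.data$x), y = quote(.data$y))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(boundary)) {
    grid <- attr(boundary, "boundary_grid")
    p <- p + ggplot2::geom_contour(
      data = grid,
      ggplot2::aes(x = .data$x, y = .data$y, z = .data$decision),
      breaks = 0, colour = "grey40", linetype = "dashed")
  }
  if ("textbook" %in% names(df)) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(colour = .data$textbook), size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(
    x = "MDS 1", y = "MDS 2",
    caption = sprintf("stress = %.3g", attr(object, "stress"))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a similarity network
#'
#' Force-directed layout of the document-similarity network, nodes
#' coloured by textbook. Edge width decreases with distance.
#'
#' @param net A `similarity_network`.
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_network <- function(net, seed = 1L) {
  nodes <- attr(net, "nodes")
  g <- igraph::graph_from_data_frame(
    as.data.frame(net[, c("from", "to", "distance")]),
    directed = FALSE, vertices = as.data.frame(nodes))
  lay <- with_perm_seed(seed, igraph::layout_with_fr(g))
  ndf <- tibble::tibble(doc_id = igraph::V(g)$name,
                        x = lay[, 1], y = lay[, 2])
  ndf <- dplyr::left_join(ndf, nodes, by = "doc_id")
  edf <- tibble::as_tibble(net) |>
    dplyr::left_join(dplyr::rename(ndf[c("doc_id", "x", "y")],
                                   x0 = "x", y0 = "y"),
                     by = c(from = "doc_id")) |>
    dplyr::left_join(dplyr::rename(ndf[c("doc_id", "x", "y")],
                                   x1 = "x", y1 = "y"),
                     by = c(to = "doc_id"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edf,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, linewidth = -.data$distance),
      colour = "grey70", show.legend = FALSE) +
    ggplot2::scale_linewidth(range = c(0.2, 1))
  if ("textbook" %in% names(ndf)) {
    p <- p + ggplot2::geom_point(
      data = ndf, ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data$textbook), size = 3)
  } else {
    p <- p + ggplot2::geom_point(
      data = ndf, ggplot2::aes(x = .data$x, y = .data$y), size = 3)
  }
  p + ggplot2::theme_void() +
    ggplot2::labs(caption = sprintf("sparsity = %.2f",
                                    attr(net, "sparsity")))
}

#' Plot contribution scores
#'
#' Bar chart of per-attribute random-forest contribution scores with
#' repeat-to-repeat standard deviation bars, facetted by task when the
#' input stacks several tasks.
#'
#' @param contributions A `contribution_report` or the stacked result of
#'   [style_contributions()].
#' @return A ggplot object.
#' @export
plot_contributions <- function(contributions) {
  df <- tibble::as_tibble(contributions)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$attribute, -.data$contribution_mean),
    y = .data$contribution_mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(0, .data$contribution_mean - .data$contribution_sd),
      ymax = .data$contribution_mean + .data$contribution_sd),
      width = 0.2) +
    ggplot2::labs(x = NULL, y = "contribution score") +
    ggplot2::theme_minimal()
  if ("task" %in% names(df)) p <- p + ggplot2::facet_wrap(~task)
  p
}

#' Plot a network sparsity sweep
#'
#' Same-textbook and same-disease edge retention fractions against
#' sparsity: whichever curve stays high at strict sparsity identifies
#' the grouping that dominates the closest document pairs.
#'
#' @param sweep Result of [network_sweep()].
#' @return A ggplot object.
#' @export
plot_network_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(sweep,
                              c("textbook_fraction", "disease_fraction"),
                              names_to = "grouping",
                              values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$sparsity, y = .data$fraction,
    colour = .data$grouping)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "sparsity (fraction of edges kept)",
                  y = "within-group edge fraction") +
    ggplot2::theme_minimal()
}
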