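# ggplot2 views of the result objects. Graph topology is the product of the
# analysis; the drawings here are diagnostic, not publication layouts.

#' Plot a corpus report
#'
#' `type = "composition"` draws the reuse composition bar (pairs per reuse
#' kind plus overlap); `type = "overlap"` draws the ontologies with the
#' highest percentage of overlapping terms.
#'
#' @param object An `ortho_report`.
#' @param type `"composition"` or `"overlap"`.
#' @param top_n Number of ontologies shown for `type = "overlap"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ortho_report <- function(object, type = c("composition", "overlap"),
                                  top_n = 10L, ...) {
  type <- match.arg(type)
  if (type == "composition") {
    df <- tibble(
      kind = factor(c(names(object$reuse_counts), "OVERLAP"),
                    levels = c("SAME_ID", "INTENDED_ID", "XREF", "OVERLAP")),
      n_pairs = c(unname(object$reuse_counts), object$overlap_count),
      class = c(rep("reuse", length(object$reuse_counts)), "overlap")
    )
    ggplot2::ggplot(df, ggplot2::aes(x = .data$kind, y = .data$n_pairs,
                                     fill = .data$class)) +
      ggplot2::geom_col() +
      ggplot2::labs(
        title = sprintf("Mapping composition, %s",
                        format(object$snapshot_date)),
        x = NULL, y = "mapping pairs", fill = NULL) +
      ggplot2::theme_minimal()
  } else {
    df <- table_overlap(object) |> utils::head(top_n)
    df$ontology_key <- stats::reorder(df$ontology_key,
                                      df$percent_overlapping)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$percent_overlapping,
                                     y = .data$ontology_key)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(
        title = sprintf("Most-overlapping ontologies, %s",
                        format(object$snapshot_date)),
        x = "% of terms overlapping", y = NULL) +
      ggplot2::theme_minimal()
  }
}

plot_graph_gg <- function(g, title, edge_label = NULL) {
  # reproducible layout without touching the caller's RNG stream
  xy <- withr::with_seed(igraph::gorder(g), igraph::layout_with_fr(g))
  nodes <- tibble(name = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  el <- igraph::as_edgelist(g)
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(el)) {
    edges <- tibble(
      x = nodes$x[match(el[, 1], nodes$name)],
      y = nodes$y[match(el[, 1], nodes$name)],
      xend = nodes$x[match(el[, 2], nodes$name)],
      yend = nodes$y[match(el[, 2], nodes$name)])
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "grey50")
  }
  p +
    ggplot2::geom_point(size = 3, colour = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$name), vjust = -1,
                       size = 3) +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot the reuse graph
#'
#' Nodes are ontologies; an arrow from reuser to source marks at least one
#' reuse pair.
#'
#' @param report An `ortho_report`.
#' @return A ggplot object.
#' @export
plot_reuse_graph <- function(report) {
  g <- build_reuse_graph(report)
  plot_graph_gg(g, sprintf("Reuse relationships, %s (%d reusers, %d sources)",
                           format(report$snapshot_date),
                           igraph::graph_attr(g, "n_reusers"),
                           igraph::graph_attr(g, "n_sources")))
}

#' Plot a threshold overlap graph
#'
#' An arrow O1 -> O2 marks that at least `threshold` of O1's terms overlap
#' with terms of O2.
#'
#' @param report An `ortho_report`.
#' @param threshold Fraction in (0, 1].
#' @return A ggplot object.
#' @export
plot_overlap_graph <- function(report, threshold = 0.30) {
  g <- build_overlap_graph(report, threshold)
  plot_graph_gg(g, sprintf("Overlap at >= %d%%, %s",
                           round(100 * threshold),
                           format(report$snapshot_date)))
}
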