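#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_segment geom_tile
#'   geom_col geom_text labs theme_minimal scale_fill_gradient coord_flip
#'   scale_colour_manual
#' @export
ggplot2::autoplot

#' Plot a hierarchical similarity DAG
#'
#' Leaves (the input sets) along the bottom, higher-order intersections on
#' rows by level; nodes carrying emphasis genes are highlighted.
#'
#' @param object A [build_hisim_dag()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hisim_dag <- function(object, ...) {
  nodes <- object$nodes
  pos <- do.call(rbind, lapply(split(seq_len(nrow(nodes)), nodes$level), function(idx) {
    data.frame(row = idx, x = seq_along(idx) - (length(idx) + 1) / 2)
  }))
  nodes$x <- pos$x[order(pos$row)]
  nodes$y <- nodes$level
  nodes$emphasized <- vapply(nodes$emphasis, length, integer(1L)) > 0L
  edges <- object$edges
  edges$x <- nodes$x[match(edges$from, nodes$node_id)]
  edges$y <- nodes$y[match(edges$from, nodes$node_id)]
  edges$xend <- nodes$x[match(edges$to, nodes$node_id)]
  edges$yend <- nodes$y[match(edges$to, nodes$node_id)]
  ggplot(nodes, aes(x = .data$x, y = .data$y)) +
    geom_segment(
      data = edges,
      aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      colour = "grey60"
    ) +
    geom_point(aes(colour = .data$emphasized), size = 3) +
    geom_text(aes(label = .data$label), vjust = -1, size = 3) +
    scale_colour_manual(values = c(`FALSE` = "steelblue", `TRUE` = "firebrick"),
                        name = "emphasis") +
    labs(x = NULL, y = "intersection level",
         title = "Hierarchical gene-set similarity graph") +
    theme_minimal()
}

#' Plot a thresholded bipartite gene-set graph
#'
#' Set nodes on the top row, gene nodes on the bottom ordered by degree with
#' the most connected genes rightmost, membership edges between.
#'
#' @param object A [threshold_subgraph()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gene_set_graph <- function(object, ...) {
  sets <- data.frame(
    id = object$set_nodes, kind = "set",
    x = seq_along(object$set_nodes), y = 2
  )
  genes <- data.frame(
    id = object$gene_nodes$gene_id, kind = "gene",
    x = seq_len(nrow(object$gene_nodes)), y = 1
  )
  if (nrow(genes) > 0L && length(sets$x) > 0L) {
    genes$x <- genes$x * max(sets$x) / (nrow(genes) + 1)
  }
  nodes <- rbind(sets, genes)
  edges <- as.data.frame(object$edges)
  edges$x <- sets$x[match(edges$set_id, sets$id)]
  edges$xend <- genes$x[match(edges$gene_id, genes$id)]
  ggplot(nodes, aes(x = .data$x, y = .data$y)) +
    geom_segment(
      data = edges,
      aes(x = .data$x, y = 2, xend = .data$xend, yend = 1),
      colour = "grey70"
    ) +
    geom_point(aes(colour = .data$kind), size = 3) +
    geom_text(aes(label = .data$id), vjust = -1, size = 3) +
    labs(x = NULL, y = NULL,
         title = sprintf("Gene set graph (min degree %d)", object$threshold)) +
    theme_minimal()
}

#' Plot a gene degree table
#'
#' @param object A [degree_table()] result.
#' @param top Show at most this many highest-degree genes.
#' @param ... Unused.
#' @return A ggplot bar chart of set counts per gene.
#' @export
autoplot.degree_table <- function(object, top = 30L, ...) {
  df <- head(as.data.frame(object), top)
  df$gene_id <- factor(df$gene_id, levels = rev(df$gene_id))
  ggplot(df, aes(x = .data$gene_id, y = .data$degree)) +
    geom_col(fill = "steelblue") +
    coord_flip() +
    labs(x = NULL, y = "number of containing sets",
         title = "Gene connectivity (degree)") +
    theme_minimal()
}

#' Plot pairwise Jaccard similarities as a heatmap
#'
#' @param object A [jaccard_matrix()] result.
#' @param ... Unused.
#' @return A ggplot tile heatmap (symmetric completion of the pair list).
#' @export
autoplot.setweaver_jaccard <- function(object, ...) {
  df <- as.data.frame(object)
  full <- rbind(
    df[, c("set_a", "set_b", "jaccard")],
    data.frame(set_a = df$set_b, set_b = df$set_a, jaccard = df$jaccard)
  )
  ggplot(full, aes(x = .data$set_a, y = .data$set_b, fill = .data$jaccard)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "firebrick", limits = c(0, 1)) +
    labs(x = NULL, y = NULL, title = "Pairwise Jaccard similarity") +
    theme_minimal()
}
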