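#' Tidy a PPI network into its edge table
#'
#' Returns one row per retained interaction, with both endpoints' group
#' labels joined on, broom-style.
#'
#' @param x A `ppi_network`.
#' @param ... Unused.
#' @return Tibble: `from`, `to`, `lis`, `lia`, `round`, `from_group`,
#'   `to_group`.
#' @method tidy ppi_network
#' @export
tidy.ppi_network <- function(x, ...) {
  groups <- setNames(x$nodes$group, x$nodes$id)
  x$edges |>
    dplyr::mutate(from_group = unname(groups[.data$from]),
                  to_group = unname(groups[.data$to]))
}

#' One-row summary of a PPI network
#'
#' @param x A `ppi_network`.
#' @param ... Unused.
#' @return One-row tibble: node counts per group, edge counts per round,
#'   pairs evaluated and pairs skipped for missing predictions.
#' @method glance ppi_network
#' @export
glance.ppi_network <- function(x, ...) {
  grp <- table(factor(x$nodes$group,
                      levels = c("bait", "group1", "group2", "group3")))
  rnd <- table(factor(x$edges$round, levels = 1:3))
  tibble(bait = x$manifest$bait,
         n_group1 = unname(grp[["group1"]]),
         n_group2 = unname(grp[["group2"]]),
         n_group3 = unname(grp[["group3"]]),
         n_edges = nrow(x$edges),
         n_edges_round1 = unname(rnd[["1"]]),
         n_edges_round2 = unname(rnd[["2"]]),
         n_edges_round3 = unname(rnd[["3"]]),
         n_pairs_evaluated = x$manifest$n_pairs_evaluated %||% NA_integer_,
         n_skipped = length(x$manifest$skipped_pairs %||% character()))
}

#' Plot a PPI network
#'
#' Force-directed layout (deterministic for a given `layout_seed`), nodes
#' coloured by discovery group, edge width proportional to LIS — the
#' conventional rendering where thicker edges mean stronger predicted
#' interactions.
#'
#' @param object A `ppi_network`.
#' @param layout_seed Seed for the layout only; does not touch results.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppi_network
#' @export
autoplot.ppi_network <- function(object, layout_seed = 42, ...) {
  g <- igraph::graph_from_data_frame(
    object$edges[, c("from", "to", "lis", "round")], directed = FALSE,
    vertices = object$nodes)
  xy <- withr::with_seed(layout_seed, igraph::layout_with_fr(g))
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  pos <- setNames(split(nodes[, c("x", "y")], seq_len(nrow(nodes))), nodes$id)
  edges <- object$edges |>
    dplyr::mutate(x = nodes$x[match(.data$from, nodes$id)],
                  y = nodes$y[match(.data$from, nodes$id)],
                  xend = nodes$x[match(.data$to, nodes$id)],
                  yend = nodes$y[match(.data$to, nodes$id)])
  cols <- c(bait = "#4daf4a", group1 = "#d9c29a", group2 = "#ff7f00",
            group3 = "#a6cee3")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$lis),
      colour = "grey55") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$group),
      shape = 21, size = 6) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$id),
      size = 2.5, vjust = -1.6) +
    ggplot2::scale_fill_manual(values = cols) +
    ggplot2::scale_linewidth(range = c(0.2, 2), limits = c(0, 1)) +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "Group", linewidth = "LIS")
}

#' Plot a PAE map
#'
#' Heat map of one model's predicted aligned error with the chain boundary
#' marked; low inter-chain error (blue) indicates a confident interface.
#'
#' @param pred A [pae_prediction()].
#' @return A ggplot object.
#' @export
plot_pae <- function(pred) {
  stopifnot(inherits(pred, "pae_prediction"))
  df <- tidyr::expand_grid(aligned = seq_len(nrow(pred$pae)),
                           scored = seq_len(ncol(pred$pae)))
  df$pae <- pred$pae[cbind(df$aligned, df$scored)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scored, y = .data$aligned,
                                   fill = .data$pae)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "#08306b", high = "#f7fbff",
                                 limits = c(0, pred$pae_max)) +
    ggplot2::geom_hline(yintercept = pred$len_a + 0.5, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = pred$len_a + 0.5, linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Scored residue", y = "Aligned residue",
                  fill = "PAE (Å)", title = pred$model_id) +
    ggplot2::theme_minimal()
}
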