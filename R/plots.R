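#' Volcano plot of a DEG table
#'
#' @param object a `deg_table` from [call_degs()].
#' @param ... unused.
#' @return A ggplot: log2 fold change (WT over mutant) against -log10 p,
#'   coloured by call.
#' @export
autoplot.deg_table <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data$log2fc, y = -log10(.data$p_value),
      colour = .data$call
    )
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      up_in_mutant = "#d53e4f", down_in_mutant = "#3288bd", ns = "grey70"
    )) +
    ggplot2::labs(
      x = "log2 fold change (WT / mutant)",
      y = "-log10 p-value",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Network plot
#'
#' Deterministic force-directed layout coloured by node origin; direct
#' binding edges are drawn thicker, echoing the convention of drawing
#' ChIP-supported regulator edges more heavily than plain PPI support.
#'
#' @param object a `grn` network.
#' @param layout_seed seed for the layout.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.grn <- function(object, layout_seed = 1L, ...) {
  set.seed(layout_seed)
  xy <- igraph::layout_with_fr(object)
  nodes <- tibble(
    name = igraph::V(object)$name,
    x = xy[, 1L], y = xy[, 2L],
    origin = igraph::V(object)$origin %||% "rna"
  )
  edges <- grn_edge_table(object)
  if (nrow(edges) > 0) {
    edges <- edges |>
      left_join(nodes |> select(from = "name", x1 = "x", y1 = "y"), by = "from") |>
      left_join(nodes |> select(to = "name", x2 = "x", y2 = "y"), by = "to")
  }
  pl <- ggplot2::ggplot()
  if (nrow(edges) > 0) {
    pl <- pl + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(
        x = .data$x1, y = .data$y1, xend = .data$x2, yend = .data$y2,
        linewidth = .data$kind == "direct_binding"
      ),
      colour = "grey60", show.legend = FALSE
    ) +
      ggplot2::scale_linewidth_manual(values = c(`FALSE` = 0.3, `TRUE` = 1))
  }
  pl +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$origin),
      size = 2
    ) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "origin")
}

#' Bar plot of enriched terms
#'
#' @param table an `enrich_table` from [enrich_terms()].
#' @param max_terms number of top terms to show.
#' @return A ggplot of -log10 p per term.
#' @export
plot_enrichment <- function(table, max_terms = 15) {
  tbl <- summarize_categories(table, max_terms) |>
    mutate(term_name = factor(.data$term_name, levels = rev(.data$term_name)))
  ggplot2::ggplot(
    tbl,
    ggplot2::aes(x = -log10(.data$p_value), y = .data$term_name)
  ) +
    ggplot2::geom_col(fill = "#3288bd") +
    ggplot2::labs(x = "-log10 p-value", y = NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of target-classification set sizes
#'
#' @param object a [classify_targets()] result.
#' @param ... unused.
#' @return A ggplot of the per-set gene counts.
#' @export
autoplot.target_classification <- function(object, ...) {
  tbl <- tidy(object)
  ggplot2::ggplot(
    tbl,
    ggplot2::aes(x = .data$set, y = .data$n)
  ) +
    ggplot2::geom_col(fill = "#66c2a5") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal()
}
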