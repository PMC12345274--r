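# A grn is an undirected igraph with:
#   graph attribute  regulator (node name of the central TF)
#   vertex attributes name, origin (chip/rna/both/neighbor/regulator),
#                     category, is_seed
#   edge attributes   kind (ppi/direct_binding), confidence

new_grn <- function(graph) {
  class(graph) <- unique(c("grn", class(graph)))
  graph
}

grn_regulator <- function(grn) igraph::graph_attr(grn, "regulator")

#' Export a regulatory network
#'
#' Writes a network in one of three Cytoscape-importable formats.
#' `graphml` carries every node attribute (`origin`, `category`, `is_seed`)
#' plus a boolean edge attribute `direct`, and round-trips exactly through
#' [read_network()]. `sif` uses the interaction label `pp` for PPI edges and
#' `reg` for regulator-to-target binding edges; isolated nodes are written
#' as single-token lines. `tsv` is a plain edge table.
#'
#' @param grn a network as built by [build_backbone()] and friends.
#' @param path output file path.
#' @param format one of `"graphml"`, `"sif"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(grn, path, format = c("graphml", "sif", "tsv")) {
  if (!format[[1L]] %in% c("graphml", "sif", "tsv")) {
    abort(sprintf(
      "unknown network format \"%s\"; supported: graphml, sif, tsv",
      format[[1L]]
    ))
  }
  format <- format[[1L]]
  g <- grn
  if (igraph::ecount(g) > 0) {
    kind <- igraph::edge_attr(g, "kind") %||% rep("ppi", igraph::ecount(g))
    g <- igraph::set_edge_attr(g, "direct", value = kind == "direct_binding")
  }
  if (format == "graphml") {
    class(g) <- "igraph"
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "sif") {
    writeLines(sif_lines(g), path)
  } else {
    tbl <- grn_edge_table(g)
    readr::write_tsv(tbl, path, progress = FALSE)
  }
  invisible(path)
}

sif_lines <- function(g) {
  if (igraph::ecount(g) == 0) {
    return(igraph::V(g)$name %||% character())
  }
  ends <- igraph::as_edgelist(g)
  kind <- igraph::edge_attr(g, "kind") %||% rep("ppi", nrow(ends))
  rel <- ifelse(kind == "direct_binding", "reg", "pp")
  edge_lines <- paste(ends[, 1L], rel, ends[, 2L], sep = "\t")
  isolated <- setdiff(igraph::V(g)$name, c(ends[, 1L], ends[, 2L]))
  c(edge_lines, isolated)
}

grn_edge_table <- function(g) {
  if (igraph::ecount(g) == 0) {
    return(tibble(
      from = character(), to = character(),
      kind = character(), confidence = double()
    ))
  }
  ends <- igraph::as_edgelist(g)
  tibble(
    from = ends[, 1L],
    to = ends[, 2L],
    kind = igraph::edge_attr(g, "kind") %||% rep("ppi", nrow(ends)),
    confidence = igraph::edge_attr(g, "confidence") %||% rep(NA_real_, nrow(ends))
  )
}

#' Read a GraphML network back into a grn object
#'
#' @param path a GraphML file written by [write_network()].
#' @return A `grn` igraph object with all attributes restored.
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  # normalize GraphML artefacts: the writer's internal node ids, and NaN
  # standing in for NA on edges without a confidence score
  if ("id" %in% igraph::vertex_attr_names(g)) {
    g <- igraph::delete_vertex_attr(g, "id")
  }
  conf <- igraph::edge_attr(g, "confidence")
  if (!is.null(conf)) {
    conf[is.nan(conf)] <- NA_real_
    g <- igraph::set_edge_attr(g, "confidence", value = conf)
  }
  new_grn(g)
}
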