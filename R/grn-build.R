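#' Allowed functional category labels
#'
#' The fixed palette of functional groups used to annotate core-network
#' genes.
#'
#' @return A character vector of valid category labels.
#' @export
grn_categories <- function() {
  c(
    "vegetative growth", "asexual development", "sexual development",
    "primary metabolism", "secondary metabolism", "transcription regulation",
    "unannotated"
  )
}

#' Load and filter a protein-protein interaction edge table
#'
#' Reads a STRING-style three-column table (two protein/gene identifiers
#' plus a combined confidence score), keeps edges at or above the
#' confidence threshold (inclusive, so a score of exactly 150 survives the
#' default cutoff), drops self-loops, and deduplicates unordered pairs
#' keeping the maximum confidence.
#'
#' @param x a file path (TSV with header) or a tibble with three columns:
#'   two identifier columns followed by a numeric confidence column.
#' @param min_confidence inclusive confidence threshold.
#' @return A tibble `protein_a`, `protein_b`, `confidence` with unique
#'   unordered pairs.
#' @export
load_ppi <- function(x, min_confidence = 150) {
  if (is.character(x)) {
    x <- readr::read_tsv(x, show_col_types = FALSE, progress = FALSE)
  }
  if (ncol(x) < 3L) abort("PPI table needs 3 columns: id, id, confidence")
  edges <- tibble(
    protein_a = as.character(x[[1L]]),
    protein_b = as.character(x[[2L]]),
    confidence = suppressWarnings(as.numeric(x[[3L]]))
  )
  bad <- which(is.na(edges$confidence) | is.na(edges$protein_a) |
    is.na(edges$protein_b))
  if (length(bad) > 0) {
    abort(sprintf("malformed PPI row(s) at line(s): %s",
      paste(head(bad + 1L, 5), collapse = ", ")
    ))
  }
  loops <- edges$protein_a == edges$protein_b
  if (any(loops)) {
    inform(sprintf("dropping %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  if (nrow(edges) == 0) {
    return(tibble(
      protein_a = character(), protein_b = character(),
      confidence = double()
    ))
  }
  edges |>
    mutate(
      a = pmin(.data$protein_a, .data$protein_b),
      b = pmax(.data$protein_a, .data$protein_b)
    ) |>
    group_by(.data$a, .data$b) |>
    summarise(confidence = max(.data$confidence), .groups = "drop") |>
    filter(.data$confidence >= min_confidence) |>
    rename(protein_a = "a", protein_b = "b") |>
    arrange(.data$protein_a, .data$protein_b)
}

#' Build the regulator-centred network backbone
#'
#' Restricts a confidence-filtered PPI edge list to interactions in which
#' both endpoints are regulator-associated genes (ChIP-bound and/or
#' differentially expressed), then layers a star of `direct_binding` edges
#' from the regulator to every ChIP-bound gene on top. Associated genes
#' without any surviving interaction are retained as isolated nodes. Node
#' `origin` records the evidence: `chip`, `rna`, or `both`.
#'
#' @param edges a confidence-filtered PPI tibble from [load_ppi()].
#' @param classification a [classify_targets()] result.
#' @param regulator_id node name for the regulator.
#' @return A `grn` igraph object.
#' @export
build_backbone <- function(edges, classification, regulator_id) {
  assoc <- classification$associated
  keep <- edges$protein_a %in% assoc & edges$protein_b %in% assoc
  ppi <- edges[keep, , drop = FALSE]
  nodes <- union(regulator_id, assoc)
  origin <- dplyr::case_when(
    nodes == regulator_id ~ "regulator",
    nodes %in% classification$direct ~ "both",
    nodes %in% classification$putative_direct ~ "chip",
    TRUE ~ "rna"
  )
  star <- tibble(
    from = regulator_id,
    to = classification$putative_direct,
    kind = "direct_binding",
    confidence = NA_real_
  ) |> filter(.data$to != regulator_id)
  edge_tbl <- bind_rows(
    tibble(
      from = ppi$protein_a, to = ppi$protein_b,
      kind = "ppi", confidence = ppi$confidence
    ),
    star
  )
  g <- igraph::graph_from_data_frame(
    edge_tbl,
    directed = FALSE,
    vertices = tibble(
      name = nodes, origin = origin,
      category = "unannotated", is_seed = FALSE
    )
  )
  g <- igraph::set_graph_attr(g, "regulator", regulator_id)
  new_grn(g)
}

#' Expand a network by guilt-by-association
#'
#' Adds the first neighbors of the current network: every gene adjacent (in
#' the confidence-filtered full edge list) to a network node is brought in
#' together with its connecting edges, exactly one step deep - neighbors of
#' neighbors are not added, and edges between two newly added genes are not
#' added either. New nodes get origin `neighbor`.
#'
#' @param grn a `grn`, typically from [build_backbone()].
#' @param edges the full confidence-filtered PPI tibble from [load_ppi()].
#' @return The expanded `grn`.
#' @export
gba_expand <- function(grn, edges) {
  members <- igraph::V(grn)$name
  ina <- edges$protein_a %in% members
  inb <- edges$protein_b %in% members
  bridge <- edges[xor(ina, inb), , drop = FALSE]
  if (nrow(bridge) == 0) {
    return(grn)
  }
  new_nodes <- setdiff(c(bridge$protein_a, bridge$protein_b), members)
  g <- igraph::add_vertices(grn, length(new_nodes),
    name = new_nodes, origin = "neighbor",
    category = "unannotated", is_seed = FALSE
  )
  g <- igraph::add_edges(
    g,
    rbind(bridge$protein_a, bridge$protein_b),
    kind = "ppi", confidence = bridge$confidence
  )
  new_grn(g)
}

#' Extract a core subnetwork around seed regulators
#'
#' Starts from the regulator plus the supplied seed genes and grows the
#' selection with neighbors of the seeds, ranked by degree (descending)
#' with lexicographic gene-id tie-breaking, until `size_target` nodes are
#' selected or no candidate remains. Returns the induced subgraph; seeds
#' disconnected from everything else are still retained.
#'
#' @param grn a `grn` network.
#' @param seeds character vector of seed regulator gene ids; seeds missing
#'   from the network are dropped with a warning.
#' @param size_target total node count to grow to (must be at least
#'   |seeds| + 1 for the regulator).
#' @return The induced `grn` subgraph with `is_seed` set on seed nodes.
#' @export
extract_core <- function(grn, seeds, size_target = 30) {
  nodes <- igraph::V(grn)$name
  regulator <- grn_regulator(grn)
  missing <- setdiff(seeds, nodes)
  if (length(missing) > 0) {
    warn(sprintf(
      "dropping %d seed(s) absent from the network: %s",
      length(missing), paste(missing, collapse = ", ")
    ))
    seeds <- setdiff(seeds, missing)
  }
  base <- union(regulator, seeds)
  if (size_target < length(seeds) + 1L) {
    abort(sprintf(
      "size_target (%d) smaller than seeds + regulator (%d)",
      size_target, length(seeds) + 1L
    ))
  }
  selected <- base
  if (length(selected) < size_target && length(seeds) > 0) {
    nbr <- unique(unlist(lapply(
      igraph::adjacent_vertices(grn, seeds),
      function(v) v$name
    )))
    cand <- setdiff(nbr, selected)
    if (length(cand) > 0) {
      deg <- igraph::degree(grn, v = cand)
      ord <- order(-deg, cand)
      take <- min(size_target - length(selected), length(cand))
      selected <- c(selected, cand[ord][seq_len(take)])
    }
  }
  core <- igraph::induced_subgraph(grn, selected)
  core <- igraph::set_vertex_attr(
    core, "is_seed",
    value = igraph::V(core)$name %in% seeds
  )
  core <- igraph::set_graph_attr(core, "regulator", regulator)
  new_grn(core)
}

#' Annotate network nodes with functional categories
#'
#' @param grn a `grn` network.
#' @param category_map a tibble with columns `gene_id` and `category`, or a
#'   named character vector (names = gene ids). Labels outside
#'   [grn_categories()] are a hard error; unmapped genes become
#'   `unannotated`.
#' @return The annotated `grn`.
#' @export
annotate_categories <- function(grn, category_map) {
  if (is.data.frame(category_map)) {
    map <- setNames(category_map$category, category_map$gene_id)
  } else {
    map <- category_map
  }
  bad <- setdiff(unique(unname(map)), grn_categories())
  if (length(bad) > 0) {
    abort(sprintf(
      "unknown category label(s): %s; allowed: %s",
      paste(bad, collapse = ", "), paste(grn_categories(), collapse = ", ")
    ))
  }
  nodes <- igraph::V(grn)$name
  cat_new <- unname(map[nodes])
  cat_new[is.na(cat_new)] <- "unannotated"
  new_grn(igraph::set_vertex_attr(grn, "category", value = cat_new))
}
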