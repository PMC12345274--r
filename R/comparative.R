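#' Restrict an ortholog table to one-to-one pairs
#'
#' Drops every pair involving an identifier that occurs in more than one
#' pair (on either side), so many-to-many orthology is excluded rather than
#' expanded, and reports how many pairs were removed.
#'
#' @param pairs a tibble whose first two columns are species-A and
#'   species-B gene ids.
#' @return A tibble `gene_a`, `gene_b` of strictly one-to-one pairs.
#' @export
filter_one_to_one <- function(pairs) {
  out <- tibble(
    gene_a = as.character(pairs[[1L]]),
    gene_b = as.character(pairs[[2L]])
  ) |> distinct()
  multi_a <- out$gene_a[duplicated(out$gene_a)]
  multi_b <- out$gene_b[duplicated(out$gene_b)]
  keep <- !(out$gene_a %in% multi_a) & !(out$gene_b %in% multi_b)
  if (any(!keep)) {
    inform(sprintf("dropped %d non one-to-one pair(s)", sum(!keep)))
  }
  out[keep, , drop = FALSE]
}

#' Partition two species' target sets by orthology
#'
#' A target is shared only when the ortholog PAIR has both ends in the
#' respective associated sets; a gene whose ortholog exists but is not a
#' target in the other species counts as species-specific. Consequently
#' |specific_A| = |associated_A| - |shared| and likewise for B.
#'
#' @param associated_a,associated_b character vectors of
#'   regulator-associated gene ids in the two species.
#' @param ortholog_map a one-to-one ortholog tibble (`gene_a`, `gene_b`),
#'   e.g. from [filter_one_to_one()].
#' @return A `target_partition` object: `shared` (tibble of pairs),
#'   `specific_a`, `specific_b` (character vectors).
#' @export
partition_targets <- function(associated_a, associated_b, ortholog_map) {
  associated_a <- check_character_set(associated_a, "associated_a")
  associated_b <- check_character_set(associated_b, "associated_b")
  map <- tibble(
    gene_a = as.character(ortholog_map[[1L]]),
    gene_b = as.character(ortholog_map[[2L]])
  )
  if (anyDuplicated(map$gene_a) || anyDuplicated(map$gene_b)) {
    abort("ortholog map is not one-to-one; run filter_one_to_one() first")
  }
  shared <- map |>
    filter(.data$gene_a %in% associated_a, .data$gene_b %in% associated_b) |>
    arrange(.data$gene_a)
  structure(
    list(
      shared = shared,
      specific_a = setdiff(associated_a, shared$gene_a),
      specific_b = setdiff(associated_b, shared$gene_b)
    ),
    class = "target_partition"
  )
}

#' @export
print.target_partition <- function(x, ...) {
  cat(sprintf(
    "<target_partition> shared pairs: %d | A-specific: %d | B-specific: %d\n",
    nrow(x$shared), length(x$specific_a), length(x$specific_b)
  ))
  invisible(x)
}

#' Merge two species networks into a comparative network
#'
#' Collapses each shared ortholog pair into a single node (carrying both
#' ids), merges the two regulator nodes into one central regulator, and
#' labels every node with a `side` in `shared` / `A_specific` /
#' `B_specific` and every edge with its species provenance (`A`, `B`, or
#' `both` when the same collapsed pair is linked in both species). The two
#' species' gene-id namespaces must be disjoint apart from ortholog pairs.
#'
#' @param grn_a,grn_b `grn` networks for the two species.
#' @param partition a [partition_targets()] result.
#' @param regulator_name node name for the merged central regulator.
#' @return A merged `grn` with node attributes `side`, `id_a`, `id_b` and
#'   edge attribute `provenance`.
#' @export
build_comparative_network <- function(grn_a, grn_b, partition,
                                      regulator_name = "regulator") {
  reg_a <- grn_regulator(grn_a)
  reg_b <- grn_regulator(grn_b)
  names_a <- setdiff(igraph::V(grn_a)$name, reg_a)
  names_b <- setdiff(igraph::V(grn_b)$name, reg_b)
  collide <- intersect(names_a, names_b)
  if (length(collide) > 0) {
    abort(sprintf(
      "gene-id collision between species namespaces (no ortholog pairing): %s",
      paste(head(collide, 5), collapse = ", ")
    ))
  }
  shared <- partition$shared
  merged_id_a <- setNames(paste(shared$gene_a, shared$gene_b, sep = "|"),
    shared$gene_a
  )
  merged_id_b <- setNames(paste(shared$gene_a, shared$gene_b, sep = "|"),
    shared$gene_b
  )
  relabel <- function(ids, reg, merged) {
    out <- ids
    out[ids == reg] <- regulator_name
    hit <- ids %in% names(merged)
    out[hit] <- unname(merged[ids[hit]])
    out
  }
  edges_of <- function(g, reg, merged, side) {
    tbl <- grn_edge_table(g)
    if (nrow(tbl) == 0) {
      return(tbl |> mutate(provenance = character()))
    }
    tbl |>
      mutate(
        from = relabel(.data$from, reg, merged),
        to = relabel(.data$to, reg, merged),
        provenance = side
      )
  }
  ea <- edges_of(grn_a, reg_a, merged_id_a, "A")
  eb <- edges_of(grn_b, reg_b, merged_id_b, "B")
  all_edges <- bind_rows(ea, eb) |>
    mutate(
      lo = pmin(.data$from, .data$to),
      hi = pmax(.data$from, .data$to)
    ) |>
    group_by(.data$lo, .data$hi, .data$kind) |>
    summarise(
      confidence = max(.data$confidence),
      provenance = if (dplyr::n_distinct(.data$provenance) > 1) "both" else .data$provenance[[1L]],
      .groups = "drop"
    ) |>
    rename(from = "lo", to = "hi")
  node_ids <- unique(c(
    regulator_name,
    relabel(names_a, reg_a, merged_id_a),
    relabel(names_b, reg_b, merged_id_b)
  ))
  side <- dplyr::case_when(
    node_ids == regulator_name ~ "regulator",
    grepl("|", node_ids, fixed = TRUE) ~ "shared",
    node_ids %in% names_a ~ "A_specific",
    TRUE ~ "B_specific"
  )
  split_pair <- stringr::str_split_fixed(node_ids, stringr::fixed("|"), 2)
  vertices <- tibble(
    name = node_ids,
    side = side,
    id_a = if_else(side == "shared", split_pair[, 1L],
      if_else(side == "A_specific", node_ids, NA_character_)
    ),
    id_b = if_else(side == "shared", split_pair[, 2L],
      if_else(side == "B_specific", node_ids, NA_character_)
    )
  )
  g <- igraph::graph_from_data_frame(
    all_edges |> select("from", "to", "kind", "confidence", "provenance"),
    directed = FALSE, vertices = vertices
  )
  g <- igraph::set_graph_attr(g, "regulator", regulator_name)
  new_grn(g)
}
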