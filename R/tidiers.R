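# broom-style tidiers for the package's result objects

#' Tidy a target classification into per-set counts
#'
#' @param x a [classify_targets()] result.
#' @param ... unused.
#' @return A tibble `set`, `n`, `pct_universe` (one-decimal percent of the
#'   annotated universe), one row per gene set.
#' @export
tidy.target_classification <- function(x, ...) {
  sets <- c("putative_direct", "degs", "direct", "indirect", "associated")
  tibble(
    set = sets,
    n = vapply(sets, function(s) length(x[[s]]), integer(1)),
    pct_universe = vapply(
      sets, function(s) percent_of(length(x[[s]]), x$n_universe), double(1)
    )
  )
}

#' One-row summary of a target classification
#'
#' @param x a [classify_targets()] result.
#' @param ... unused.
#' @return A one-row tibble with the five set sizes, the universe size and
#'   the percent of the universe that is ChIP-bound.
#' @export
glance.target_classification <- function(x, ...) {
  tibble(
    n_putative_direct = length(x$putative_direct),
    n_degs = length(x$degs),
    n_direct = length(x$direct),
    n_indirect = length(x$indirect),
    n_associated = length(x$associated),
    n_universe = x$n_universe,
    pct_bound = percent_of(length(x$putative_direct), x$n_universe)
  )
}

#' Tidy a comparative target partition
#'
#' @param x a [partition_targets()] result.
#' @param ... unused.
#' @return A tibble `side`, `n` for shared / A-specific / B-specific.
#' @export
tidy.target_partition <- function(x, ...) {
  tibble(
    side = c("shared", "A_specific", "B_specific"),
    n = c(nrow(x$shared), length(x$specific_a), length(x$specific_b))
  )
}

#' One-row summary of a comparative target partition
#'
#' @param x a [partition_targets()] result.
#' @param ... unused.
#' @return A one-row tibble `n_shared`, `n_specific_a`, `n_specific_b`.
#' @export
glance.target_partition <- function(x, ...) {
  tibble(
    n_shared = nrow(x$shared),
    n_specific_a = length(x$specific_a),
    n_specific_b = length(x$specific_b)
  )
}

#' Tidy a network into its edge table
#'
#' @param x a `grn` network.
#' @param ... unused.
#' @return A tibble `from`, `to`, `kind`, `confidence`.
#' @export
tidy.grn <- function(x, ...) {
  grn_edge_table(x)
}

#' One-row summary of a network
#'
#' @param x a `grn` network.
#' @param ... unused.
#' @return A one-row tibble with node/edge counts, the number of direct
#'   binding edges and the regulator name.
#' @export
glance.grn <- function(x, ...) {
  kind <- if (igraph::ecount(x) > 0) {
    igraph::edge_attr(x, "kind") %||% rep("ppi", igraph::ecount(x))
  } else {
    character()
  }
  tibble(
    n_nodes = igraph::vcount(x),
    n_edges = igraph::ecount(x),
    n_direct_edges = sum(kind == "direct_binding"),
    regulator = grn_regulator(x) %||% NA_character_
  )
}

#' Node table of a network
#'
#' @param grn a `grn` network.
#' @return A tibble of node names and attributes.
#' @export
grn_nodes <- function(grn) {
  as_tibble(igraph::as_data_frame(grn, what = "vertices"))
}

#' One-row summary of a motif enrichment test
#'
#' @param x a [motif_enrichment()] result.
#' @param ... unused.
#' @return A one-row tibble `statistic`, `p_value`, `n_permutations`,
#'   `n_bound`, `n_background`.
#' @export
glance.motif_enrichment <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    p_value = x$p_value,
    n_permutations = x$n_permutations,
    n_bound = x$n_bound,
    n_background = x$n_background
  )
}
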