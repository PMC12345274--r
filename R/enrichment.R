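#' Hypergeometric over-representation of annotation terms
#'
#' Classic one-sided term enrichment: for each term with `K` annotated
#' genes in a universe of `N`, the probability of seeing at least the
#' observed `k` annotated genes in a query of size `n` by chance is the
#' upper-tail hypergeometric probability P(X >= k). Terms with p below
#' `alpha` are returned, sorted by ascending p-value, then descending
#' number of associated query genes, then term id. No term-hierarchy
#' propagation is performed: annotations are taken as flat gene-to-term
#' sets.
#'
#' @param query character vector of gene ids (must lie inside `universe`).
#' @param annotation a tibble with columns `gene_id`, `term_id` and
#'   optionally `term_name`.
#' @param universe character vector of all annotated-universe gene ids.
#' @param alpha significance cutoff (strict `<`); no multiple-testing
#'   correction is applied by default, use `adjust = "BH"` to threshold
#'   Benjamini-Hochberg adjusted values instead.
#' @param adjust `"none"` or `"BH"`.
#' @return An `enrich_table` tibble: `term_id`, `term_name`, `k`, `K`, `n`,
#'   `N`, `p_value` (and `p_adjusted`).
#' @export
enrich_terms <- function(query, annotation, universe, alpha = 0.05,
                         adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  query <- check_character_set(query, "query")
  universe <- check_character_set(universe, "universe")
  bad <- setdiff(query, universe)
  if (length(bad) > 0) {
    abort(sprintf(
      "query contains %d gene(s) outside the universe, e.g. %s",
      length(bad), paste(head(bad, 3), collapse = ", ")
    ))
  }
  ann <- tibble(
    gene_id = as.character(annotation$gene_id),
    term_id = as.character(annotation$term_id),
    term_name = if ("term_name" %in% names(annotation)) {
      as.character(annotation$term_name)
    } else {
      as.character(annotation$term_id)
    }
  ) |>
    filter(.data$gene_id %in% universe) |>
    distinct(.data$gene_id, .data$term_id, .keep_all = TRUE)
  N <- length(universe)
  n <- length(query)
  stats <- ann |>
    group_by(.data$term_id, .data$term_name) |>
    summarise(
      K = n(),
      k = sum(.data$gene_id %in% query),
      .groups = "drop"
    ) |>
    mutate(
      n = n, N = N,
      p_value = phyper(.data$k - 1, .data$K, N - .data$K, n,
        lower.tail = FALSE
      )
    ) |>
    mutate(p_adjusted = p.adjust(.data$p_value, method = "BH"))
  p_cut <- if (adjust == "BH") stats$p_adjusted else stats$p_value
  out <- stats[p_cut < alpha, , drop = FALSE] |>
    arrange(.data$p_value, desc(.data$k), .data$term_id) |>
    select(
      "term_id", "term_name", "k", "K", "n", "N", "p_value", "p_adjusted"
    )
  class(out) <- c("enrich_table", class(out))
  out
}

#' Pick the most representative enriched terms
#'
#' Deterministic "representative category" selection: the top rows of the
#' enrichment table under its (p ascending, gene count descending) order.
#'
#' @param table an `enrich_table` from [enrich_terms()].
#' @param max_terms number of terms to keep.
#' @return The first `max_terms` rows (fewer when the table is shorter).
#' @export
summarize_categories <- function(table, max_terms) {
  head(table, max_terms)
}
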