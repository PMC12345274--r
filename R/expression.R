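#' Keep genes expressed in every sample
#'
#' Retains genes whose FPKM is strictly positive in every sample of every
#' condition supplied, i.e. genes quantified with full coverage across
#' samples. Gene order is preserved.
#'
#' @param ... one or more wide expression tibbles (first column `gene_id`,
#'   remaining columns per-sample FPKM) sharing the same gene universe.
#' @return The filtered tibble when one table is given, otherwise a list of
#'   filtered tibbles in input order. Warns (does not error) when no gene
#'   survives.
#' @export
filter_expressed <- function(...) {
  mats <- list(...)
  if (length(mats) == 0) abort("supply at least one expression table")
  ids <- mats[[1L]]$gene_id
  for (m in mats[-1L]) {
    if (!identical(m$gene_id, ids)) {
      abort("expression tables must share the same genes in the same order")
    }
  }
  keep <- rep(TRUE, length(ids))
  for (m in mats) {
    v <- as_sample_matrix(m, "gene_id")
    keep <- keep & rowSums(v > 0) == ncol(v)
  }
  if (!any(keep)) warn("no gene is expressed in every sample")
  out <- purrr::map(mats, ~ .x[keep, , drop = FALSE])
  if (length(out) == 1L) out[[1L]] else out
}

#' Quantile-normalize an expression table
#'
#' Forces every sample column onto the same distribution: after
#' normalization each column's sorted values equal the per-rank mean across
#' columns. Ties within a column receive the mean of the normalized values
#' of their tied ranks (the mean-of-tied-ranks dialect; dialects differ, so
#' this is stated explicitly).
#'
#' @param x a wide expression tibble (first column `gene_id`).
#' @return The normalized tibble, same shape and order. A single-column
#'   table is returned unchanged with a warning.
#' @export
quantile_normalize <- function(x) {
  m <- as_sample_matrix(x, "gene_id")
  if (ncol(m) < 2L) {
    warn("quantile normalization needs >= 2 columns; returning input unchanged")
    return(x)
  }
  q <- quantile_normalize_matrix(m)
  out <- x
  out[, colnames(m)] <- as_tibble(q)
  out
}

quantile_normalize_matrix <- function(m) {
  mu <- rowMeans(apply(m, 2L, sort))
  q <- apply(m, 2L, function(col) {
    v <- numeric(length(col))
    v[order(col)] <- mu
    # ties: average the reference values assigned to equal inputs
    ave(v, col, FUN = mean)
  })
  dimnames(q) <- dimnames(m)
  q
}

#' Call differentially expressed genes between two conditions
#'
#' Implements a dual-threshold rule: a gene is called when its two-sided
#' equal-variance (Student) t-test p-value is below `deg_p_threshold` AND
#' its raw-FPKM fold change exceeds `deg_fold_threshold`, both strict
#' inequalities. The t-test runs on quantile-normalized values of the
#' combined matrix (so both conditions share one reference distribution),
#' while the fold change is computed on raw condition means with a small
#' pseudocount. The log2 fold change is log2(mean WT / mean mutant): a
#' negative value means the gene is up in the mutant (repressed by the
#' regulator in WT), a positive value means down in the mutant.
#'
#' @param wt,mutant wide FPKM tibbles (first column `gene_id`) with >= 2
#'   replicate columns each, sharing the same gene universe.
#' @param config a [pipeline_config()].
#' @param normalize run the t-test on quantile-normalized values (default)
#'   or on raw FPKM.
#' @param adjust `"none"` (default; raw p-values are thresholded) or `"BH"`
#'   (Benjamini-Hochberg adjusted p-values are thresholded instead).
#' @return A `deg_table` tibble sorted by ascending p-value: `gene_id`,
#'   `log2fc`, `p_value`, `p_adjusted`, `call` with
#'   `call` in `up_in_mutant` / `down_in_mutant` / `ns`.
#' @export
call_degs <- function(wt, mutant, config = pipeline_config(),
                      normalize = TRUE, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!setequal(wt$gene_id, mutant$gene_id)) {
    abort("conditions must share the same gene universe")
  }
  mutant <- mutant[match(wt$gene_id, mutant$gene_id), , drop = FALSE]
  mw <- as_sample_matrix(wt, "gene_id")
  mm <- as_sample_matrix(mutant, "gene_id")
  if (ncol(mw) < 2L || ncol(mm) < 2L) {
    abort("each condition needs at least 2 replicates")
  }
  eps <- config$deg_pseudocount
  log2fc <- log2((rowMeans(mw) + eps) / (rowMeans(mm) + eps))
  if (normalize) {
    q <- quantile_normalize_matrix(cbind(mw, mm))
    tw <- q[, seq_len(ncol(mw)), drop = FALSE]
    tm <- q[, ncol(mw) + seq_len(ncol(mm)), drop = FALSE]
  } else {
    tw <- mw
    tm <- mm
  }
  tt <- row_t_test(tw, tm)
  p_adj <- p.adjust(tt$p_value, method = "BH")
  p_for_call <- if (adjust == "BH") p_adj else tt$p_value
  lfc_cut <- log2(config$deg_fold_threshold)
  call <- dplyr::case_when(
    p_for_call < config$deg_p_threshold & log2fc < -lfc_cut ~ "up_in_mutant",
    p_for_call < config$deg_p_threshold & log2fc > lfc_cut ~ "down_in_mutant",
    TRUE ~ "ns"
  )
  out <- tibble(
    gene_id = wt$gene_id,
    log2fc = unname(log2fc),
    p_value = tt$p_value,
    p_adjusted = p_adj,
    call = call
  ) |>
    arrange(.data$p_value)
  class(out) <- c("deg_table", class(out))
  out
}

#' Summarise a DEG table
#'
#' Counts up/down calls and reports them as a percentage of the annotated
#' gene universe, the way genome-wide differential-expression figures are
#' usually labelled.
#'
#' @param degs a `deg_table` from [call_degs()].
#' @param n_universe number of annotated genes in the species.
#' @return A one-row tibble: `n_up`, `n_down`, `n_deg`, `pct_of_universe`
#'   (one-decimal percent).
#' @export
deg_summary <- function(degs, n_universe) {
  n_up <- sum(degs$call == "up_in_mutant")
  n_down <- sum(degs$call == "down_in_mutant")
  tibble(
    n_up = n_up,
    n_down = n_down,
    n_deg = n_up + n_down,
    pct_of_universe = percent_of(n_up + n_down, n_universe)
  )
}

#' Cross-complementation rescue accounting
#'
#' Compares two direction-labelled DEG sets called against the same mutant
#' reference: the native WT-vs-mutant set and the cross-complemented
#' strain-vs-mutant set. Per direction it reports the size of the cross set,
#' its overlap with the WT set, and the WT genes the cross-complementation
#' failed to rescue (WT minus cross).
#'
#' @param deg_wt,deg_cross tibbles with columns `gene_id` and `direction`
#'   (values `up` or `down`), from the same gene universe.
#' @return A tibble with one row per direction: `direction`, `n_cross`,
#'   `n_overlap`, `n_wt_specific`.
#' @export
classify_rescue <- function(deg_wt, deg_cross) {
  for (d in list(deg_wt, deg_cross)) {
    bad <- setdiff(unique(d$direction), c("up", "down"))
    if (length(bad) > 0) {
      abort(sprintf(
        "direction labels must be 'up' or 'down'; found: %s",
        paste(bad, collapse = ", ")
      ))
    }
  }
  purrr::map_dfr(c("up", "down"), function(dir) {
    wt <- deg_wt$gene_id[deg_wt$direction == dir]
    cx <- deg_cross$gene_id[deg_cross$direction == dir]
    tibble(
      direction = dir,
      n_cross = length(cx),
      n_overlap = length(intersect(cx, wt)),
      n_wt_specific = length(setdiff(wt, cx))
    )
  })
}
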