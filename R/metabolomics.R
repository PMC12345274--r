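#' Call differentially abundant metabolite features
#'
#' A feature is eligible when its mean intensity exceeds the intensity gate
#' (default 1e6) in at least one condition, so a metabolite absent from one
#' genotype remains callable. Eligible features are tested with a
#' two-sided equal-variance t-test on log10(intensity + 1); the fold change
#' is log2(mean WT / mean mutant) on raw intensities with a pseudocount of
#' 1. Calls require p < `metab_p_threshold` and |log2 fold change| >
#' `metab_log2fc_threshold`, both strict; negative log2 fold change means
#' the feature accumulates in the mutant.
#'
#' @param wt,mutant feature tibbles with columns `feature_id`, `mz`, `rt`
#'   followed by >= 2 replicate intensity columns, sharing the same
#'   features in the same order.
#' @param config a [pipeline_config()].
#' @return A tibble `feature_id`, `mz`, `rt`, `mean_wt`, `mean_mutant`,
#'   `eligible`, `log2fc`, `p_value`, `call` with `call` in
#'   `increased_in_mutant` / `decreased_in_mutant` / `ns`. Ineligible
#'   features carry `NA` p-values and `ns`.
#' @export
call_differential_features <- function(wt, mutant, config = pipeline_config()) {
  id_cols <- c("feature_id", "mz", "rt")
  if (!identical(wt$feature_id, mutant$feature_id)) {
    abort("conditions must share the same features in the same order")
  }
  mw <- as_sample_matrix(wt, id_cols)
  mm <- as_sample_matrix(mutant, id_cols)
  if (ncol(mw) < 2L || ncol(mm) < 2L) {
    abort("each condition needs at least 2 replicates")
  }
  mean_wt <- rowMeans(mw)
  mean_mut <- rowMeans(mm)
  eligible <- mean_wt > config$metab_min_intensity |
    mean_mut > config$metab_min_intensity
  log2fc <- log2((mean_wt + 1) / (mean_mut + 1))
  tt <- row_t_test(log10(mw + 1), log10(mm + 1))
  p <- tt$p_value
  p[!eligible] <- NA_real_
  call <- dplyr::case_when(
    !eligible | is.na(p) ~ "ns",
    p < config$metab_p_threshold &
      log2fc < -config$metab_log2fc_threshold ~ "increased_in_mutant",
    p < config$metab_p_threshold &
      log2fc > config$metab_log2fc_threshold ~ "decreased_in_mutant",
    TRUE ~ "ns"
  )
  tibble(
    feature_id = wt$feature_id,
    mz = wt$mz,
    rt = wt$rt,
    mean_wt = unname(mean_wt),
    mean_mutant = unname(mean_mut),
    eligible = unname(eligible),
    log2fc = unname(log2fc),
    p_value = unname(p),
    call = call
  )
}

#' Presence/absence classification of metabolite features
#'
#' A feature is detected in a condition when its mean intensity exceeds the
#' detection threshold; the four classes record in which genotypes it is
#' detected.
#'
#' @param wt,mutant feature tibbles as in [call_differential_features()].
#' @param threshold detection threshold on the mean intensity (strict `>`;
#'   defaults to the differential-calling intensity gate).
#' @return A tibble `feature_id`, `detected_wt`, `detected_mutant`, `class`
#'   with `class` in `wt_only` / `mutant_only` / `both` / `neither`.
#' @export
classify_presence <- function(wt, mutant, threshold = 1e6) {
  id_cols <- c("feature_id", "mz", "rt")
  if (!identical(wt$feature_id, mutant$feature_id)) {
    abort("conditions must share the same features in the same order")
  }
  dw <- rowMeans(as_sample_matrix(wt, id_cols)) > threshold
  dm <- rowMeans(as_sample_matrix(mutant, id_cols)) > threshold
  tibble(
    feature_id = wt$feature_id,
    detected_wt = unname(dw),
    detected_mutant = unname(dm),
    class = dplyr::case_when(
      dw & dm ~ "both",
      dw & !dm ~ "wt_only",
      !dw & dm ~ "mutant_only",
      TRUE ~ "neither"
    )
  )
}

#' Identify features against a compound library by exact mass
#'
#' A feature matches a compound when the absolute difference between the
#' feature m/z and the library monoisotopic mass is at most
#' `mass_tolerance` (inclusive at exactly the tolerance) and, when the
#' library supplies a reference retention time, |delta RT| is within
#' `rt_tolerance`. A feature may match several compounds; all matches are
#' reported, sorted by ascending mass error. Masses are compared as given
#' (neutral-mass comparison); adduct handling, when needed, is applied to
#' the library beforehand.
#'
#' @param features a feature tibble with `feature_id`, `mz`, `rt`.
#' @param library a compound tibble with `compound`, `mass` and optionally
#'   `ref_rt` (NA = no retention-time constraint).
#' @param config a [pipeline_config()] supplying `mass_tolerance` and
#'   `rt_tolerance`.
#' @return A tibble `feature_id`, `compound`, `mz`, `mass`, `mass_error`,
#'   `rt`, `ref_rt` sorted by `mass_error`.
#' @export
identify_compounds <- function(features, library, config = pipeline_config()) {
  if (nrow(library) == 0) abort("compound library is empty")
  if (!"ref_rt" %in% names(library)) library$ref_rt <- NA_real_
  pairs <- tidyr::crossing(
    features |> select("feature_id", "mz", "rt"),
    library |> select("compound", "mass", "ref_rt")
  ) |>
    mutate(mass_error = abs(.data$mz - .data$mass)) |>
    filter(
      .data$mass_error <= config$mass_tolerance,
      is.na(.data$ref_rt) | abs(.data$rt - .data$ref_rt) <= config$rt_tolerance
    ) |>
    arrange(.data$mass_error, .data$feature_id, .data$compound) |>
    select(
      "feature_id", "compound", "mz", "mass", "mass_error", "rt", "ref_rt"
    )
  pairs
}
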