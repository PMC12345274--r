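#' Pipeline configuration
#'
#' Collects every tunable threshold of the integration pipeline in one
#' validated list. The defaults encode the analysis conventions the package
#' implements throughout: a dual differential-expression threshold (raw
#' two-sided p < 0.05 from an equal-variance t-test together with a greater
#' than two-fold change), a 1.5 kb promoter window upstream of the
#' translation start site for peak-to-gene assignment, an inclusive
#' STRING-style confidence cutoff of 150 for protein-protein interaction
#' edges, intensity/fold/p gates for metabolite differential calling, and
#' exact-mass (0.001 Da) plus retention-time (1.5 units) tolerances for
#' compound identification.
#'
#' @param deg_p_threshold p-value cutoff for differential expression
#'   (strict `<`).
#' @param deg_fold_threshold fold-change cutoff on raw FPKM condition means
#'   (strict `>`, on the ratio scale; 2 means |log2 fold change| > 1).
#' @param deg_pseudocount pseudocount added to both condition means before
#'   the ratio, preventing infinite fold changes.
#' @param promoter_window promoter window length in bases, measured strictly
#'   upstream of the translation start site.
#' @param ppi_min_confidence minimum STRING-style combined confidence score
#'   for a PPI edge (inclusive `>=`).
#' @param metab_p_threshold,metab_log2fc_threshold,metab_min_intensity
#'   metabolite differential-calling gates: p-value cutoff (strict `<`),
#'   |log2 fold change| cutoff (strict `>`) and the mean peak-intensity gate
#'   a feature must exceed in at least one condition (strict `>`).
#' @param mass_tolerance exact-mass tolerance in Da for compound
#'   identification (inclusive).
#' @param rt_tolerance retention-time tolerance (inclusive), in the units of
#'   the feature table (minutes for typical LC-MS runs).
#' @param nre_motif the regulator's DNA binding element scanned in promoter
#'   sequences; the GATA-factor element GATCT by default.
#' @param core_size_target number of genes a core subnetwork is grown to.
#' @param rng_seed integer seed used by stochastic stages.
#' @return A validated list with class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config()
#' cfg$promoter_window
#' @export
pipeline_config <- function(deg_p_threshold = 0.05,
                            deg_fold_threshold = 2,
                            deg_pseudocount = 0.01,
                            promoter_window = 1500,
                            ppi_min_confidence = 150,
                            metab_p_threshold = 0.05,
                            metab_log2fc_threshold = 1,
                            metab_min_intensity = 1e6,
                            mass_tolerance = 0.001,
                            rt_tolerance = 1.5,
                            nre_motif = "GATCT",
                            core_size_target = 30,
                            rng_seed = 1L) {
  cfg <- list(
    deg_p_threshold = deg_p_threshold,
    deg_fold_threshold = deg_fold_threshold,
    deg_pseudocount = deg_pseudocount,
    promoter_window = promoter_window,
    ppi_min_confidence = ppi_min_confidence,
    metab_p_threshold = metab_p_threshold,
    metab_log2fc_threshold = metab_log2fc_threshold,
    metab_min_intensity = metab_min_intensity,
    mass_tolerance = mass_tolerance,
    rt_tolerance = rt_tolerance,
    nre_motif = nre_motif,
    core_size_target = core_size_target,
    rng_seed = as.integer(rng_seed)
  )
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  num <- c(
    "deg_p_threshold", "deg_fold_threshold", "promoter_window",
    "ppi_min_confidence", "metab_p_threshold", "metab_log2fc_threshold",
    "metab_min_intensity", "mass_tolerance", "rt_tolerance",
    "core_size_target"
  )
  for (f in num) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      abort(sprintf("config field `%s` must be a single positive number", f))
    }
  }
  if (!is.numeric(cfg$deg_pseudocount) || cfg$deg_pseudocount < 0) {
    abort("config field `deg_pseudocount` must be non-negative")
  }
  motif <- toupper(cfg$nre_motif)
  if (!nzchar(motif) || grepl("[^ACGT]", motif)) {
    abort("config field `nre_motif` must be a non-empty string over {A,C,G,T}")
  }
  cfg$nre_motif <- motif
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Fields present in the file override the defaults of [pipeline_config()];
#' unknown fields are rejected so typos do not silently fall back to a
#' default.
#'
#' @param path path to a YAML file whose top-level keys are
#'   [pipeline_config()] arguments.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    abort(sprintf(
      "unknown config field(s): %s", paste(extra, collapse = ", ")
    ))
  }
  do.call(pipeline_config, raw)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (f in names(x)) cat(sprintf("  %-24s %s\n", f, format(x[[f]])))
  invisible(x)
}
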