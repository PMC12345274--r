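#' Specification for the synthetic two-species multi-omics dataset
#'
#' Collects every parameter of the synthetic-data generator. The defaults
#' define the standard study conditions the package is validated under:
#' 2,000 genes per species on two chromosomes, three replicates per
#' condition, log-normal FPKM baselines (meanlog 2, sdlog 1) with
#' multiplicative log-normal replicate noise (sdlog 0.25), planted
#' differential genes at four-fold so the dual p/fold screen has high power
#' at n = 3, ChIP peaks planted strand-correctly inside the 1.5 kb promoter
#' window (with decoy peaks at least 2 kb upstream), a stochastic-block PPI
#' graph whose within-module confidences are Uniform(150, 999) and
#' between-module Uniform(50, 400), a 60% one-to-one ortholog overlap, and
#' a 500-feature metabolome with eight-fold planted shifts.
#'
#' @param n_genes genes per species.
#' @param n_chromosomes chromosomes the genes are tiled over.
#' @param gene_length gene body length in bases.
#' @param intergenic intergenic spacing in bases (>= 3000; the default 6000
#'   keeps decoy peaks out of every neighbouring promoter window).
#' @param n_replicates replicates per condition (>= 2).
#' @param frac_deg_up,frac_deg_down fractions of genes planted as
#'   up-/down-regulated in the mutant.
#' @param deg_fold planted expression fold change (>= 4 recommended so the
#'   two-fold + t-test screen recovers the plants at n = 3).
#' @param frac_zero fraction of genes given zero FPKM in some samples
#'   (dropped by the full-coverage filter).
#' @param baseline_meanlog,baseline_sdlog log-normal law of per-gene
#'   baseline FPKM.
#' @param noise_sdlog sdlog of the multiplicative replicate noise.
#' @param frac_bound fraction of genes planted as ChIP-bound (one peak
#'   fully inside the promoter window).
#' @param frac_decoy fraction of genes given a decoy peak entirely >=
#'   `decoy_offset` bases upstream of the translation start.
#' @param peak_width planted peak width in bases.
#' @param promoter_window promoter window length in bases.
#' @param decoy_offset minimum upstream distance of decoy peaks.
#' @param motif regulator binding element planted in bound promoters.
#' @param motif_planted number of motif copies planted per bound promoter.
#' @param motif_background_rate Bernoulli probability that a background
#'   promoter gets one planted copy (on top of chance occurrences).
#' @param ppi_n_modules,ppi_p_within,ppi_p_between stochastic block model:
#'   number of modules and within/between edge probabilities.
#' @param ppi_conf_within,ppi_conf_between uniform confidence-score ranges
#'   for within- and between-module edges.
#' @param ortholog_shared_fraction fraction of the smaller gene universe
#'   mapped one-to-one to the other species.
#' @param n_features metabolite features per species.
#' @param frac_feature_diff fraction of features with a planted abundance
#'   shift.
#' @param feature_shift_log2 planted |log2 shift| (>= 2).
#' @param feature_meanlog,feature_sdlog log-normal law of baseline feature
#'   intensity.
#' @param frac_library fraction of features whose m/z is placed within
#'   0.0005 Da of a library mass.
#' @param frac_wt_only,frac_mutant_only fractions of features zeroed in
#'   exactly one condition.
#' @param n_library compounds in the synthetic library.
#' @param rng_seed integer seed; the whole generator is a pure function of
#'   (spec, seed).
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 2000,
                           n_chromosomes = 2,
                           gene_length = 1500,
                           intergenic = 6000,
                           n_replicates = 3,
                           frac_deg_up = 0.05,
                           frac_deg_down = 0.05,
                           deg_fold = 4,
                           frac_zero = 0.02,
                           baseline_meanlog = 2,
                           baseline_sdlog = 1,
                           noise_sdlog = 0.25,
                           frac_bound = 0.05,
                           frac_decoy = 0.05,
                           peak_width = 200,
                           promoter_window = 1500,
                           decoy_offset = 2000,
                           motif = "GATCT",
                           motif_planted = 2,
                           motif_background_rate = 0.3,
                           ppi_n_modules = 20,
                           ppi_p_within = 0.2,
                           ppi_p_between = 0.002,
                           ppi_conf_within = c(150, 999),
                           ppi_conf_between = c(50, 400),
                           ortholog_shared_fraction = 0.6,
                           n_features = 500,
                           frac_feature_diff = 0.1,
                           feature_shift_log2 = 3,
                           feature_meanlog = log(5e6),
                           feature_sdlog = 1,
                           frac_library = 0.2,
                           frac_wt_only = 0.02,
                           frac_mutant_only = 0.02,
                           n_library = 100,
                           rng_seed = 1L) {
  spec <- as.list(environment())
  fracs <- c(
    "frac_deg_up", "frac_deg_down", "frac_zero", "frac_bound", "frac_decoy",
    "motif_background_rate", "ppi_p_within", "ppi_p_between",
    "ortholog_shared_fraction", "frac_feature_diff", "frac_library",
    "frac_wt_only", "frac_mutant_only"
  )
  for (f in fracs) {
    v <- spec[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      abort(sprintf("spec field `%s` must be a fraction in [0, 1]", f))
    }
  }
  if (spec$n_replicates < 2) abort("n_replicates must be >= 2")
  if (spec$deg_fold <= 1) abort("deg_fold must exceed 1")
  if (spec$feature_shift_log2 <= 0) abort("feature_shift_log2 must be > 0")
  if (spec$intergenic < 3000) abort("intergenic spacing must be >= 3000")
  if (grepl("[^ACGT]", toupper(spec$motif))) {
    abort("motif must be over {A,C,G,T}")
  }
  spec$motif <- toupper(spec$motif)
  spec$rng_seed <- as.integer(spec$rng_seed)
  structure(spec, class = "synthetic_spec")
}

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
      collapse = ""
    )
  }, character(1))
}

plant_motif <- function(seq, motif, n_copies) {
  w <- nchar(motif)
  L <- nchar(seq)
  # non-overlapping slots spaced a motif-width-plus-one apart
  slots <- seq(1L, L - w, by = w + 1L)
  pos <- sample(slots, min(n_copies, length(slots)))
  for (p in pos) {
    substr(seq, p, p + w - 1L) <- motif
  }
  seq
}

#' Generate one synthetic species dataset
#'
#' Tiled gene models on several chromosomes (both strands, intergenic
#' spacing well above 3 kb), promoter sequences with planted regulator
#' binding elements, ChIP peaks planted strand-correctly inside (bound
#' genes) or well upstream of (decoy genes) the promoter window, and
#' replicate FPKM tables for WT and mutant with planted fold effects. The
#' planted ground truth is returned alongside the data.
#'
#' @param spec a [synthetic_spec()].
#' @param prefix gene-id prefix, which also namespaces chromosome names.
#' @param seed integer seed (defaults to `spec$rng_seed`).
#' @return A list: `genes` (gene-model tibble), `promoters`
#'   ([Biostrings::DNAStringSet] named by gene), `peaks` (peak tibble),
#'   `fpkm_wt`, `fpkm_mutant` (wide FPKM tibbles), `chrom_lengths`, and
#'   `truth` (planted DEGs with direction, bound genes, decoy genes,
#'   zeroed genes).
#' @export
simulate_species <- function(spec = synthetic_spec(), prefix = "SPA",
                             seed = spec$rng_seed) {
  set.seed(seed)
  n <- spec$n_genes
  ids <- sprintf("%s%05d", prefix, seq_len(n))
  chrom_idx <- rep(seq_len(spec$n_chromosomes), length.out = n)
  chrom_idx <- sort(chrom_idx)
  chrom <- sprintf("%s_chr%d", prefix, chrom_idx)
  margin <- 10000L
  pitch <- spec$gene_length + spec$intergenic
  pos_in_chrom <- unlist(lapply(
    table(chrom_idx),
    function(k) seq_len(k) - 1L
  ), use.names = FALSE)
  start <- margin + pos_in_chrom * pitch
  end <- start + spec$gene_length
  strand <- sample(c("+", "-"), n, replace = TRUE)
  ts <- ifelse(strand == "+", start, end - 1L)
  genes <- tibble(
    gene_id = ids, chrom = chrom,
    start = as.integer(start), end = as.integer(end),
    strand = strand, translation_start = as.integer(ts)
  )
  chrom_lengths <- tapply(end, chrom, max) + margin
  chrom_lengths <- setNames(as.integer(chrom_lengths), names(chrom_lengths))

  # planted gene classes (DEG up/down, bound, decoy, zeroed) --------------
  n_up <- round(spec$frac_deg_up * n)
  n_down <- round(spec$frac_deg_down * n)
  n_zero <- round(spec$frac_zero * n)
  deg_pool <- sample(ids, n_up + n_down + n_zero)
  up <- deg_pool[seq_len(n_up)]
  down <- deg_pool[n_up + seq_len(n_down)]
  zero_genes <- deg_pool[n_up + n_down + seq_len(n_zero)]
  bound <- sort(sample(ids, round(spec$frac_bound * n)))
  decoy <- sort(sample(setdiff(ids, bound), round(spec$frac_decoy * n)))

  # peaks ------------------------------------------------------------------
  w <- spec$peak_width
  win <- spec$promoter_window
  peak_row <- function(gid, inside) {
    g <- genes[genes$gene_id == gid, ]
    if (inside) {
      off <- sample.int(win - w, 1L) - 1L
      s <- if (g$strand == "+") g$translation_start - win + off else g$translation_start + 1L + off
    } else {
      extra <- sample.int(300L, 1L)
      s <- if (g$strand == "+") {
        g$translation_start - spec$decoy_offset - w - extra
      } else {
        g$translation_start + 1L + spec$decoy_offset + extra
      }
    }
    tibble(
      chrom = g$chrom, start = as.integer(s), end = as.integer(s + w),
      name = paste0("peak_", gid), score = round(runif(1, 50, 1000), 1),
      summit = as.integer(s + w %/% 2L)
    )
  }
  peaks <- bind_rows(
    purrr::map(bound, peak_row, inside = TRUE),
    purrr::map(decoy, peak_row, inside = FALSE)
  )
  if (nrow(peaks) > 0 &&
    any(peaks$start < 0 | peaks$end > chrom_lengths[peaks$chrom])) {
    abort("spacing constraint unsatisfiable: a planted peak fell outside its chromosome")
  }

  # promoters with planted motif occurrences -------------------------------
  prom <- random_dna(n, win)
  is_bound <- ids %in% bound
  prom[is_bound] <- vapply(
    prom[is_bound],
    plant_motif,
    character(1),
    motif = spec$motif, n_copies = spec$motif_planted
  )
  bg_plant <- !is_bound & rbinom(n, 1L, spec$motif_background_rate) == 1L
  prom[bg_plant] <- vapply(
    prom[bg_plant],
    plant_motif,
    character(1),
    motif = spec$motif, n_copies = 1L
  )
  promoters <- Biostrings::DNAStringSet(setNames(prom, ids))

  # FPKM with planted fold effects ------------------------------------------
  base <- rlnorm(n, spec$baseline_meanlog, spec$baseline_sdlog)
  fold <- rep(1, n)
  fold[ids %in% up] <- spec$deg_fold # up in mutant
  fold[ids %in% down] <- 1 / spec$deg_fold
  reps <- spec$n_replicates
  noise <- function() {
    matrix(rlnorm(n * reps, 0, spec$noise_sdlog), n, reps)
  }
  mat_wt <- base * noise()
  mat_mut <- (base * fold) * noise()
  for (g in which(ids %in% zero_genes)) {
    cond <- sample(c("wt", "mut"), 1L)
    j <- sample.int(reps, sample.int(reps, 1L))
    if (cond == "wt") mat_wt[g, j] <- 0 else mat_mut[g, j] <- 0
  }
  colnames(mat_wt) <- paste0("wt_", seq_len(reps))
  colnames(mat_mut) <- paste0("mut_", seq_len(reps))
  fpkm_wt <- bind_cols(tibble(gene_id = ids), as_tibble(mat_wt))
  fpkm_mutant <- bind_cols(tibble(gene_id = ids), as_tibble(mat_mut))

  list(
    genes = genes,
    promoters = promoters,
    peaks = peaks,
    fpkm_wt = fpkm_wt,
    fpkm_mutant = fpkm_mutant,
    chrom_lengths = chrom_lengths,
    truth = list(
      deg = bind_rows(
        tibble(gene_id = up, direction = "up_in_mutant"),
        tibble(gene_id = down, direction = "down_in_mutant")
      ),
      bound = bound,
      decoy = decoy,
      zero_genes = zero_genes
    )
  )
}

#' Generate a stochastic-block-model PPI table
#'
#' Nodes are split evenly into modules; edges appear with probability
#' `ppi_p_within` inside a module and `ppi_p_between` across modules.
#' Within-module edges get Uniform(`ppi_conf_within`) confidence scores and
#' between-module edges Uniform(`ppi_conf_between`), so filtering at the
#' default threshold of 150 keeps all within-module edges and a closed-form
#' fraction of between-module ones. No self-loops, each unordered pair at
#' most once.
#'
#' @param spec a [synthetic_spec()].
#' @param nodes character vector of node (gene) ids.
#' @param seed integer seed.
#' @return A list: `edges` (tibble `protein_a`, `protein_b`,
#'   `confidence`) and `modules` (tibble `gene_id`, `module`).
#' @export
simulate_ppi <- function(spec = synthetic_spec(), nodes,
                         seed = spec$rng_seed) {
  if (length(nodes) == 0) abort("node universe is empty")
  set.seed(seed)
  n <- length(nodes)
  m <- min(spec$ppi_n_modules, n)
  sizes <- rep(n %/% m, m)
  sizes[seq_len(n %% m)] <- sizes[seq_len(n %% m)] + 1L
  pref <- matrix(spec$ppi_p_between, m, m)
  diag(pref) <- spec$ppi_p_within
  g <- igraph::sample_sbm(n, pref.matrix = pref, block.sizes = sizes)
  module <- rep(seq_len(m), sizes)
  perm <- sample.int(n) # detach module structure from node-id order
  node_of <- nodes[perm]
  el <- igraph::as_edgelist(g, names = FALSE)
  same <- module[el[, 1L]] == module[el[, 2L]]
  conf <- numeric(nrow(el))
  conf[same] <- runif(sum(same), spec$ppi_conf_within[1L], spec$ppi_conf_within[2L])
  conf[!same] <- runif(sum(!same), spec$ppi_conf_between[1L], spec$ppi_conf_between[2L])
  edges <- tibble(
    protein_a = node_of[el[, 1L]],
    protein_b = node_of[el[, 2L]],
    confidence = round(conf, 1)
  )
  list(
    edges = edges,
    modules = tibble(gene_id = node_of, module = module) |>
      arrange(.data$gene_id)
  )
}

#' Generate a one-to-one ortholog map between two gene universes
#'
#' Samples `round(shared_fraction * min(|A|, |B|))` strictly one-to-one
#' pairs.
#'
#' @param ids_a,ids_b gene-id universes of the two species.
#' @param shared_fraction fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return A tibble `gene_a`, `gene_b`.
#' @export
simulate_ortholog_map <- function(ids_a, ids_b, shared_fraction = 0.6,
                                  seed = 1L) {
  if (shared_fraction < 0 || shared_fraction > 1) {
    abort("shared_fraction must be in [0, 1]")
  }
  set.seed(seed)
  n_pairs <- round(shared_fraction * min(length(ids_a), length(ids_b)))
  tibble(
    gene_a = sample(ids_a, n_pairs),
    gene_b = sample(ids_b, n_pairs)
  ) |> arrange(.data$gene_a)
}

#' Generate a synthetic metabolite feature table pair plus compound library
#'
#' Log-normal baseline intensities with multiplicative replicate noise;
#' planted differential features get a |log2 shift| of
#' `feature_shift_log2`; `frac_wt_only` / `frac_mutant_only` features are
#' zeroed in exactly one condition; `frac_library` of the features have
#' their m/z placed within 0.0005 Da of a library mass so they are
#' identifiable under the 0.001 Da tolerance.
#'
#' @param spec a [synthetic_spec()].
#' @param prefix feature-id prefix.
#' @param seed integer seed.
#' @return A list: `wt`, `mutant` (feature tibbles), `library` (tibble
#'   `compound`, `mass`, `ref_rt`), and `truth` (differential features
#'   with direction, wt-only / mutant-only ids, library-matched ids).
#' @export
simulate_metabolome <- function(spec = synthetic_spec(), prefix = "M",
                                seed = spec$rng_seed) {
  set.seed(seed)
  nf <- spec$n_features
  reps <- spec$n_replicates
  ids <- sprintf("%s%04d", prefix, seq_len(nf))
  library_tbl <- tibble(
    compound = sprintf("compound_%03d", seq_len(spec$n_library)),
    mass = round(runif(spec$n_library, 150, 1500), 4),
    ref_rt = NA_real_
  )
  mz <- round(runif(nf, 150, 1500), 4)
  n_lib <- round(spec$frac_library * nf)
  lib_features <- sample(ids, n_lib)
  lib_idx <- match(lib_features, ids)
  mz[lib_idx] <- round(
    sample(library_tbl$mass, n_lib, replace = TRUE) +
      runif(n_lib, -5e-4, 5e-4),
    4
  )
  rt <- round(runif(nf, 1, 20), 2)
  n_diff <- round(spec$frac_feature_diff * nf)
  n_wt_only <- round(spec$frac_wt_only * nf)
  n_mut_only <- round(spec$frac_mutant_only * nf)
  special <- sample(ids, n_diff + n_wt_only + n_mut_only)
  diff_ids <- special[seq_len(n_diff)]
  wt_only <- special[n_diff + seq_len(n_wt_only)]
  mut_only <- special[n_diff + n_wt_only + seq_len(n_mut_only)]
  direction <- sample(c("increased_in_mutant", "decreased_in_mutant"),
    n_diff,
    replace = TRUE
  )
  base <- rlnorm(nf, spec$feature_meanlog, spec$feature_sdlog)
  shift <- rep(1, nf)
  di <- match(diff_ids, ids)
  shift[di] <- ifelse(direction == "increased_in_mutant",
    2^spec$feature_shift_log2, 2^-spec$feature_shift_log2
  )
  noise <- function() matrix(rlnorm(nf * reps, 0, spec$noise_sdlog), nf, reps)
  mat_wt <- base * noise()
  mat_mut <- (base * shift) * noise()
  mat_mut[match(wt_only, ids), ] <- 0
  mat_wt[match(mut_only, ids), ] <- 0
  colnames(mat_wt) <- paste0("wt_", seq_len(reps))
  colnames(mat_mut) <- paste0("mut_", seq_len(reps))
  head_tbl <- tibble(feature_id = ids, mz = mz, rt = rt)
  list(
    wt = bind_cols(head_tbl, as_tibble(mat_wt)),
    mutant = bind_cols(head_tbl, as_tibble(mat_mut)),
    library = library_tbl,
    truth = list(
      differential = tibble(feature_id = diff_ids, direction = direction),
      wt_only = wt_only,
      mutant_only = mut_only,
      library_features = sort(lib_features)
    )
  )
}

#' Generate the full two-species study
#'
#' Convenience wrapper producing both species datasets, their PPI tables,
#' the ortholog map, and both metabolomes, all deterministically derived
#' from `spec$rng_seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return A list: `species_a`, `species_b` (from [simulate_species()]),
#'   `ppi_a`, `ppi_b`, `orthologs`, `metabolome_a`, `metabolome_b`.
#' @export
simulate_study <- function(spec = synthetic_spec()) {
  s <- spec$rng_seed
  sp_a <- simulate_species(spec, prefix = "SPA", seed = s)
  sp_b <- simulate_species(spec, prefix = "SPB", seed = s + 1L)
  list(
    species_a = sp_a,
    species_b = sp_b,
    ppi_a = simulate_ppi(spec, sp_a$genes$gene_id, seed = s + 2L),
    ppi_b = simulate_ppi(spec, sp_b$genes$gene_id, seed = s + 3L),
    orthologs = simulate_ortholog_map(
      sp_a$genes$gene_id, sp_b$genes$gene_id,
      spec$ortholog_shared_fraction,
      seed = s + 4L
    ),
    metabolome_a = simulate_metabolome(spec, prefix = "MA", seed = s + 5L),
    metabolome_b = simulate_metabolome(spec, prefix = "MB", seed = s + 6L)
  )
}

#' Write a self-contained synthetic dataset directory
#'
#' Emits exactly the on-disk formats the readers consume - GFF3 annotation,
#' promoter FASTA, narrowPeak peaks, per-condition FPKM and metabolite
#' TSVs, PPI and ortholog TSVs - plus a `ground_truth.json` with every
#' planted entity. Deterministic: the same spec and seed produce identical
#' files.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
simulate_dataset <- function(spec = synthetic_spec(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  study <- simulate_study(spec)
  p <- function(...) file.path(dir, paste0(...))
  for (side in c("a", "b")) {
    sp <- study[[paste0("species_", side)]]
    write_annotation(sp$genes, p("species_", side, ".gff3"))
    Biostrings::writeXStringSet(sp$promoters, p("promoters_", side, ".fasta"))
    write_peaks(sp$peaks, p("peaks_", side, ".narrowPeak"))
    readr::write_tsv(sp$fpkm_wt, p("fpkm_wt_", side, ".tsv"), progress = FALSE)
    readr::write_tsv(sp$fpkm_mutant, p("fpkm_mutant_", side, ".tsv"),
      progress = FALSE
    )
    readr::write_tsv(study[[paste0("ppi_", side)]]$edges,
      p("ppi_", side, ".tsv"),
      progress = FALSE
    )
    met <- study[[paste0("metabolome_", side)]]
    readr::write_tsv(met$wt, p("metab_wt_", side, ".tsv"), progress = FALSE)
    readr::write_tsv(met$mutant, p("metab_mutant_", side, ".tsv"),
      progress = FALSE
    )
    readr::write_tsv(met$library, p("library_", side, ".tsv"),
      progress = FALSE
    )
  }
  readr::write_tsv(study$orthologs, p("orthologs.tsv"), progress = FALSE)
  truth <- list(
    species_a = study$species_a$truth,
    species_b = study$species_b$truth,
    metabolome_a = study$metabolome_a$truth,
    metabolome_b = study$metabolome_b$truth,
    ppi_modules_a = study$ppi_a$modules,
    ppi_modules_b = study$ppi_b$modules
  )
  jsonlite::write_json(truth, p("ground_truth.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
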