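small_spec <- function(...) synthetic_spec(n_genes = 200, ...)

test_that("the generator is deterministic: same spec + seed, identical files", {
  spec <- small_spec(n_features = 60, n_library = 20)
  d1 <- file.path(tempdir(), "sim1")
  d2 <- file.path(tempdir(), "sim2")
  simulate_dataset(spec, d1)
  simulate_dataset(spec, d2)
  for (f in list.files(d1)) {
    expect_identical(
      readLines(file.path(d1, f)), readLines(file.path(d2, f)),
      info = f
    )
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("planted ground truth is consistent with the emitted files", {
  spec <- small_spec(n_features = 60, n_library = 20)
  d <- file.path(tempdir(), "sim_truth")
  simulate_dataset(spec, d)
  genes <- read_annotation(file.path(d, "species_a.gff3"))
  expect_equal(nrow(genes), spec$n_genes)
  truth <- jsonlite::read_json(file.path(d, "ground_truth.json"),
    simplifyVector = TRUE
  )
  expect_true(all(truth$species_a$bound %in% genes$gene_id))
  expect_true(all(truth$species_a$deg$gene_id %in% genes$gene_id))
  peaks <- read_peaks(file.path(d, "peaks_a.narrowPeak"))
  expect_equal(nrow(peaks), length(truth$species_a$bound) +
    length(truth$species_a$decoy))
  wt <- readr::read_tsv(file.path(d, "fpkm_wt_a.tsv"), show_col_types = FALSE)
  expect_setequal(wt$gene_id, genes$gene_id)
  prom <- Biostrings::readDNAStringSet(file.path(d, "promoters_a.fasta"))
  expect_setequal(names(prom), genes$gene_id)
  met_wt <- readr::read_tsv(file.path(d, "metab_wt_a.tsv"),
    show_col_types = FALSE
  )
  expect_true(all(truth$metabolome_a$differential$feature_id %in%
    met_wt$feature_id))
  unlink(d, recursive = TRUE)
})

test_that("genes keep >= 3 kb intergenic spacing on both strands", {
  sp <- simulate_species(small_spec(), "SP", seed = 3)
  by_chrom <- split(sp$genes, sp$genes$chrom)
  expect_gte(length(by_chrom), 2L)
  for (g in by_chrom) {
    g <- g[order(g$start), ]
    if (nrow(g) > 1) {
      expect_true(all(g$start[-1] - g$end[-nrow(g)] >= 3000))
    }
  }
  expect_setequal(unique(sp$genes$strand), c("+", "-"))
})

test_that("planted peaks sit inside promoter windows, decoys >= 2 kb upstream", {
  sp <- simulate_species(small_spec(), "SP", seed = 5)
  win <- promoter_windows(sp$genes, 1500)
  for (gid in sp$truth$bound) {
    w <- win[win$gene_id == gid, ]
    p <- sp$peaks[sp$peaks$name == paste0("peak_", gid), ]
    expect_true(p$start >= w$start && p$end <= w$end)
  }
  for (gid in sp$truth$decoy) {
    g <- sp$genes[sp$genes$gene_id == gid, ]
    p <- sp$peaks[sp$peaks$name == paste0("peak_", gid), ]
    dist <- if (g$strand == "+") {
      g$translation_start - p$end
    } else {
      p$start - g$translation_start
    }
    expect_gte(dist, 2000)
  }
})

test_that("bound promoters carry at least the planted motif copies", {
  sp <- simulate_species(small_spec(), "SP", seed = 6)
  sc <- scan_motif(sp$promoters, "GATCT")
  bound_counts <- sc$count[sc$seq_id %in% sp$truth$bound]
  expect_true(all(bound_counts >= 2))
})

test_that("an unplaceable peak layout is a hard error", {
  # decoy offset so large the peaks would fall before the chromosome start
  expect_error(
    simulate_species(small_spec(decoy_offset = 50000), "SP", seed = 1),
    "unsatisfiable"
  )
})

test_that("a null expression dataset calls ~5% of genes at p < 0.05", {
  spec <- synthetic_spec(
    n_genes = 1000, frac_deg_up = 0, frac_deg_down = 0,
    frac_zero = 0
  )
  sp <- simulate_species(spec, "SP", seed = 11)
  degs <- call_degs(sp$fpkm_wt, sp$fpkm_mutant)
  hits <- sum(degs$p_value < 0.05)
  expect_gte(hits, qbinom(0.005, 1000, 0.05))
  expect_lte(hits, qbinom(0.995, 1000, 0.05))
})

test_that("SBM extremes give a complete graph / module components", {
  ids <- sprintf("g%02d", 1:12)
  one <- simulate_ppi(
    synthetic_spec(ppi_n_modules = 1, ppi_p_within = 1),
    ids,
    seed = 2
  )
  expect_equal(nrow(one$edges), choose(12, 2))
  expect_true(all(one$edges$protein_a != one$edges$protein_b))

  split4 <- simulate_ppi(
    synthetic_spec(ppi_n_modules = 4, ppi_p_within = 1, ppi_p_between = 0),
    ids,
    seed = 2
  )
  g <- igraph::graph_from_data_frame(split4$edges[, 1:2], directed = FALSE)
  comp <- igraph::components(g)
  expect_equal(comp$no, 4L)
})

test_that("confidence filtering matches the uniform-mixture expectation", {
  set.seed(14)
  ids <- sprintf("g%04d", 1:1200)
  spec <- synthetic_spec(
    ppi_n_modules = 12, ppi_p_within = 0.25, ppi_p_between = 0.012
  )
  ppi <- simulate_ppi(spec, ids, seed = 15)
  n_edges <- nrow(ppi$edges)
  expect_gt(n_edges, 10000)
  kept <- nrow(load_ppi(ppi$edges, min_confidence = 150))
  # within-module scores are Uniform(150, 999) -> all kept;
  # between-module Uniform(50, 400) -> (400-150)/350 kept
  g <- igraph::graph_from_data_frame(ppi$edges[, 1:2], directed = FALSE)
  mod <- setNames(ppi$modules$module, ppi$modules$gene_id)
  same <- mod[ppi$edges$protein_a] == mod[ppi$edges$protein_b]
  expected <- sum(same) + (250 / 350) * sum(!same)
  expect_lt(abs(kept - expected) / n_edges, 0.05)
})

test_that("ortholog maps have the requested one-to-one size", {
  a <- sprintf("a%03d", 1:100)
  b <- sprintf("b%03d", 1:200)
  expect_equal(nrow(simulate_ortholog_map(a, b, 0, seed = 1)), 0L)
  m <- simulate_ortholog_map(a, a, 1, seed = 1)
  expect_equal(nrow(m), 100L)
  expect_equal(anyDuplicated(m$gene_a), 0L)
  expect_equal(anyDuplicated(m$gene_b), 0L)
  expect_equal(nrow(simulate_ortholog_map(a, b, 0.5, seed = 1)), 50L)
  expect_error(simulate_ortholog_map(a, b, 1.5), "\\[0, 1\\]")
})

test_that("metabolome plants are recovered and nulls stay calibrated", {
  spec <- small_spec(n_features = 400)
  met <- simulate_metabolome(spec, seed = 21)
  res <- call_differential_features(met$wt, met$mutant)
  hit <- res$feature_id[res$call != "ns"]
  expect_gte(
    mean(met$truth$differential$feature_id %in% hit), 0.9
  )
  dir_called <- res$call[match(met$truth$differential$feature_id, res$feature_id)]
  agree <- dir_called == met$truth$differential$direction
  expect_gte(mean(agree[dir_called != "ns"]), 0.99)

  pres <- classify_presence(met$wt, met$mutant)
  expect_true(all(
    pres$class[match(met$truth$wt_only, pres$feature_id)] == "wt_only"
  ))

  ids <- identify_compounds(met$wt, met$library)
  expect_true(all(met$truth$library_features %in% ids$feature_id))
  no_lib <- simulate_metabolome(small_spec(frac_library = 0), seed = 22)
  expect_equal(nrow(identify_compounds(no_lib$wt, no_lib$library)), 0L)

  null_met <- simulate_metabolome(
    small_spec(
      n_features = 400, frac_feature_diff = 0,
      frac_wt_only = 0, frac_mutant_only = 0
    ),
    seed = 23
  )
  nres <- call_differential_features(null_met$wt, null_met$mutant)
  tested <- !is.na(nres$p_value)
  hits <- sum(nres$p_value[tested] < 0.05)
  expect_gte(hits, qbinom(0.005, sum(tested), 0.05))
  expect_lte(hits, qbinom(0.995, sum(tested), 0.05))
})
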