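wide <- function(ids, m, prefix = "s") {
  colnames(m) <- paste0(prefix, "_", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(gene_id = ids), tibble::as_tibble(m))
}

test_that("filter_expressed keeps only fully covered genes", {
  m <- wide(paste0("g", 1:3), matrix(1:9, 3, 3))
  expect_identical(filter_expressed(m), m)

  # toy 5-gene pair of condition tables, 2 genes partially zero -> 3 remain
  wt <- wide(paste0("g", 1:5), matrix(c(
    1, 2, 3,
    0, 2, 3, # zero in wt
    4, 4, 4,
    5, 5, 5,
    6, 6, 6
  ), 5, 3, byrow = TRUE), "wt")
  mut <- wide(paste0("g", 1:5), matrix(c(
    1, 2, 3,
    1, 2, 3,
    4, 4, 4,
    5, 0, 5, # zero in mutant
    6, 6, 6
  ), 5, 3, byrow = TRUE), "mut")
  out <- filter_expressed(wt, mut)
  expect_equal(out[[1]]$gene_id, c("g1", "g3", "g5"))
  expect_equal(out[[2]]$gene_id, c("g1", "g3", "g5"))

  expect_warning(
    filter_expressed(wide("g1", matrix(0, 1, 2))),
    "no gene"
  )
})

test_that("quantile normalization matches the explicit rank-mean oracle", {
  # 4x3 worked example
  m <- matrix(c(
    5, 2, 3,
    2, 1, 4,
    3, 4, 6,
    4, 8, 5
  ), 4, 3, byrow = TRUE)
  got <- quantile_normalize(wide(paste0("g", 1:4), m))
  expect_equal(
    unname(as.matrix(got[, -1])),
    unname(oracle_quantile_normalize(m))
  )
  # random matrices, including ties
  set.seed(42)
  for (i in 1:25) {
    m <- matrix(sample(1:30, 50, replace = TRUE), 10, 5)
    got <- quantile_normalize(wide(paste0("g", 1:10), m))
    expect_equal(
      unname(as.matrix(got[, -1])),
      unname(oracle_quantile_normalize(m))
    )
  }
})

test_that("quantile normalization agrees with limma on tie-free data", {
  skip_if_not_installed("limma")
  set.seed(7)
  m <- matrix(rlnorm(60, 2, 1), 12, 5)
  got <- quantile_normalize(wide(paste0("g", 1:12), m))
  expect_equal(
    unname(as.matrix(got[, -1])),
    unname(limma::normalizeQuantiles(m)),
    tolerance = 1e-12
  )
})

test_that("quantile normalization fixed points and column means", {
  m <- matrix(rep(c(4, 1, 3, 2), 3), 4, 3)
  out <- quantile_normalize(wide(paste0("g", 1:4), m))
  expect_equal(unname(as.matrix(out[, -1])), m) # identical columns unchanged
  set.seed(1)
  m2 <- matrix(rlnorm(40), 8, 5)
  out2 <- as.matrix(quantile_normalize(wide(paste0("g", 1:8), m2))[, -1])
  expect_equal(diff(range(colMeans(out2))), 0, tolerance = 1e-12)
  expect_warning(
    quantile_normalize(wide(paste0("g", 1:4), matrix(1:4, 4, 1))),
    ">= 2 columns"
  )
})

test_that("identical conditions give zero DEG calls", {
  set.seed(2)
  m <- wide(paste0("g", 1:50), matrix(rlnorm(150, 2, 1), 50, 3), "wt")
  mut <- m
  names(mut) <- sub("wt", "mut", names(mut))
  degs <- call_degs(m, mut)
  expect_true(all(degs$call == "ns"))
})

test_that("an 8-fold drop in the mutant is called down with positive log2fc", {
  set.seed(3)
  n <- 40
  base <- rlnorm(n, 3, 0.5)
  fold <- rep(1, n)
  fold[1] <- 1 / 8 # planted: strongly DOWN in the mutant
  mw <- wide(paste0("g", 1:n), base * matrix(rlnorm(n * 3, 0, 0.05), n, 3), "wt")
  mm <- wide(
    paste0("g", 1:n), (base * fold) * matrix(rlnorm(n * 3, 0, 0.05), n, 3),
    "mut"
  )
  degs <- call_degs(mw, mm)
  row <- degs[degs$gene_id == "g1", ]
  expect_equal(row$call, "down_in_mutant")
  expect_gt(row$log2fc, 0) # log2(WT/mutant) > 0 when the mutant is lower
})

test_that("swapping conditions negates log2fc and preserves p-values", {
  set.seed(4)
  n <- 30
  mw <- wide(paste0("g", 1:n), matrix(rlnorm(n * 3, 2, 1), n, 3), "wt")
  mm <- wide(paste0("g", 1:n), matrix(rlnorm(n * 3, 2, 1), n, 3), "mut")
  a <- call_degs(mw, mm)
  b <- call_degs(mm, mw)
  b <- b[match(a$gene_id, b$gene_id), ]
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$p_value, b$p_value)
})

test_that("dual thresholds are strict inequalities", {
  # build a gene sitting exactly at |log2fc| = 1 with a tiny p-value
  wt <- wide(
    c("edge", "filler1", "filler2"),
    matrix(c(
      2, 2, 2,
      5, 6, 7,
      1, 2, 3
    ), 3, 3, byrow = TRUE), "wt"
  )
  mut <- wide(
    c("edge", "filler1", "filler2"),
    matrix(c(
      1, 1, 1,
      5, 6, 7,
      1, 2, 3
    ), 3, 3, byrow = TRUE), "mut"
  )
  cfg <- pipeline_config(deg_pseudocount = 0)
  degs <- call_degs(wt, mut, config = cfg, normalize = FALSE)
  edge <- degs[degs$gene_id == "edge", ]
  expect_equal(edge$log2fc, 1) # exactly two-fold
  expect_equal(edge$call, "ns") # strict >, so not called
})

test_that("fewer than two replicates is a hard error", {
  wt <- wide(paste0("g", 1:3), matrix(1:3, 3, 1), "wt")
  mut <- wide(paste0("g", 1:3), matrix(4:6, 3, 1), "mut")
  expect_error(call_degs(wt, mut), "2 replicates")
})

test_that("null simulation keeps the p<0.05 fraction inside the 99% band", {
  set.seed(1)
  n <- 500
  reps <- 100
  hits <- 0L
  for (i in seq_len(reps)) {
    base <- rlnorm(n, 2, 1)
    mw <- wide(paste0("g", 1:n), base * matrix(rlnorm(n * 3, 0, 0.25), n, 3), "wt")
    mm <- wide(paste0("g", 1:n), base * matrix(rlnorm(n * 3, 0, 0.25), n, 3), "mut")
    degs <- call_degs(mw, mm)
    hits <- hits + sum(degs$p_value < 0.05)
  }
  total <- n * reps
  expect_gte(hits, qbinom(0.005, total, 0.05))
  expect_lte(hits, qbinom(0.995, total, 0.05))
})

test_that("rescue accounting reproduces the printed overlap triples", {
  mk <- function(n, prefix, dir) {
    tibble::tibble(gene_id = paste0(prefix, seq_len(n)), direction = dir)
  }
  # up: cross 734, WT 669 sharing 390 -> WT-specific 279
  shared_up <- mk(390, "s", "up")
  cross_up <- dplyr::bind_rows(shared_up, mk(344, "c", "up"))
  wt_up <- dplyr::bind_rows(shared_up, mk(279, "w", "up"))
  # down: cross 628, WT 569 sharing 339 -> WT-specific 230
  shared_dn <- mk(339, "S", "down")
  cross_dn <- dplyr::bind_rows(shared_dn, mk(289, "C", "down"))
  wt_dn <- dplyr::bind_rows(shared_dn, mk(230, "W", "down"))
  res <- classify_rescue(
    dplyr::bind_rows(wt_up, wt_dn),
    dplyr::bind_rows(cross_up, cross_dn)
  )
  expect_equal(res$n_cross, c(734L, 628L))
  expect_equal(res$n_overlap, c(390L, 339L))
  expect_equal(res$n_wt_specific, c(279L, 230L))

  # empty cross set: zero overlap, everything WT-specific
  empty <- tibble::tibble(gene_id = character(), direction = character())
  res2 <- classify_rescue(wt_up, empty)
  expect_equal(res2$n_overlap, c(0L, 0L))
  expect_equal(res2$n_wt_specific, c(669L, 0L))

  expect_error(
    classify_rescue(mk(2, "x", "sideways"), cross_up),
    "direction"
  )
})
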