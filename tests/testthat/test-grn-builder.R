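ppi_tbl <- function(a, b, conf) {
  tibble::tibble(protein_a = a, protein_b = b, confidence = conf)
}

test_that("PPI loading: inclusive threshold, dedup keeps max confidence", {
  f <- tempfile(fileext = ".tsv")
  readr::write_tsv(
    ppi_tbl(
      c("a", "a", "b", "c", "d"),
      c("b", "b", "a", "d", "c"),
      c(200, 300, 150, 149, 120)
    ),
    f
  )
  edges <- load_ppi(f)
  # a-b duplicated (both orders) -> one edge at max 300; b-a at 150 kept
  # (inclusive); c-d at 149/120 dropped
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$confidence, 300)

  edges2 <- load_ppi(ppi_tbl("x", "y", 150))
  expect_equal(nrow(edges2), 1L) # score exactly 150 survives ">= 150"
  expect_equal(nrow(load_ppi(ppi_tbl("x", "y", 149))), 0L)

  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("protein_a\tprotein_b\tconfidence", "a\tb\toops"), f2)
  expect_error(load_ppi(f2), "line")

  expect_message(out <- load_ppi(ppi_tbl("a", "a", 500)), "self-loop")
  expect_equal(nrow(out), 0L)
})

test_that("backbone keeps only edges with both endpoints associated", {
  uni <- sprintf("g%02d", 1:20)
  cls <- classify_targets(uni[1:4], uni[3:8], uni)
  # 6 edges, 3 with both endpoints in associated = g1..g8
  edges <- ppi_tbl(
    c("g01", "g02", "g05", "g01", "g09", "g15"),
    c("g02", "g07", "g08", "g19", "g10", "g16"),
    rep(500, 6)
  )
  bb <- build_backbone(edges, cls, "TF")
  et <- tidy(bb)
  expect_equal(sum(et$kind == "ppi"), 3L)
  expect_equal(sum(et$kind == "direct_binding"), 4L) # one per bound gene
  expect_setequal(igraph::V(bb)$name, c("TF", cls$associated))
  origins <- grn_nodes(bb)
  expect_equal(origins$origin[origins$name == "g03"], "both")
  expect_equal(origins$origin[origins$name == "g01"], "chip")
  expect_equal(origins$origin[origins$name == "g07"], "rna")

  # no qualifying PPI edge -> pure direct-binding star
  bb2 <- build_backbone(ppi_tbl("g09", "g10", 500), cls, "TF")
  expect_true(all(tidy(bb2)$kind == "direct_binding"))

  # all genes associated -> every edge survives
  cls_all <- classify_targets(uni, uni, uni)
  bb3 <- build_backbone(edges, cls_all, "TF")
  expect_equal(sum(tidy(bb3)$kind == "ppi"), nrow(edges))
})

test_that("backbone edge filtering equals brute force on random instances", {
  set.seed(21)
  for (i in 1:20) {
    uni <- sprintf("n%02d", 1:30)
    chip <- sample(uni, 6)
    deg <- sample(uni, 10)
    cls <- classify_targets(chip, deg, uni)
    a <- sample(uni, 40, replace = TRUE)
    b <- sample(uni, 40, replace = TRUE)
    keep <- a != b
    edges <- ppi_tbl(a[keep], b[keep], runif(sum(keep), 150, 999)) |>
      dplyr::distinct(pmin(protein_a, protein_b), pmax(protein_a, protein_b),
        .keep_all = TRUE
      ) |>
      dplyr::select(protein_a, protein_b, confidence)
    bb <- build_backbone(edges, cls, "TF")
    ppi_edges <- dplyr::filter(tidy(bb), kind == "ppi")
    brute <- edges[
      edges$protein_a %in% cls$associated &
        edges$protein_b %in% cls$associated,
    ]
    expect_equal(nrow(ppi_edges), nrow(brute))
  }
})

test_that("guilt-by-association expansion is exactly depth 1", {
  uni <- sprintf("g%02d", 1:20)
  cls <- classify_targets(uni[1:2], uni[2:3], uni)
  # chain g01 - g10 - g11: g10 is a first neighbor, g11 depth 2
  full <- ppi_tbl(
    c("g01", "g10", "g02"),
    c("g10", "g11", "g03"),
    rep(500, 3)
  )
  bb <- build_backbone(full, cls, "TF")
  ex <- gba_expand(bb, full)
  expect_true("g10" %in% igraph::V(ex)$name)
  expect_false("g11" %in% igraph::V(ex)$name) # neighbors of neighbors excluded
  expect_equal(
    grn_nodes(ex)$origin[grn_nodes(ex)$name == "g10"], "neighbor"
  )
  # fixed point when no external neighbor exists
  ex2 <- gba_expand(ex, ppi_tbl("g01", "g03", 500))
  expect_equal(igraph::vcount(ex2), igraph::vcount(ex))
  # applying twice differs from once exactly because depth-2 neighbors exist
  ex_twice <- gba_expand(ex, full)
  expect_true("g11" %in% igraph::V(ex_twice)$name)
})

test_that("expanded node set equals a depth-1 BFS from the backbone", {
  set.seed(31)
  for (i in 1:10) {
    uni <- sprintf("m%02d", 1:40)
    cls <- classify_targets(sample(uni, 5), sample(uni, 8), uni)
    a <- sample(uni, 60, replace = TRUE)
    b <- sample(uni, 60, replace = TRUE)
    keep <- a != b
    edges <- dplyr::distinct(ppi_tbl(
      pmin(a[keep], b[keep]), pmax(a[keep], b[keep]), 500
    ))
    bb <- build_backbone(edges, cls, "TF")
    ex <- gba_expand(bb, edges)
    expect_setequal(
      igraph::V(ex)$name,
      oracle_bfs1(igraph::V(bb)$name, edges)
    )
  }
})

test_that("core extraction is deterministic with degree/lexicographic ranking", {
  uni <- sprintf("g%02d", 1:20)
  cls <- classify_targets(uni[1:3], uni[1:3], uni[1:3])
  edges <- ppi_tbl("g01", "g02", 500)
  bb <- build_backbone(edges, cls, "TF")
  core <- extract_core(bb, seeds = c("g01", "g02"), size_target = 3)
  expect_setequal(igraph::V(core)$name, c("TF", "g01", "g02"))
  expect_error(extract_core(bb, seeds = c("g01", "g02"), size_target = 2), "size_target")

  # clique of 50 + 2 seeds: symmetric degrees force lexicographic tie-break
  ids <- sprintf("k%02d", 1:50)
  pairs <- t(utils::combn(ids, 2))
  clique <- ppi_tbl(pairs[, 1], pairs[, 2], 500)
  cls2 <- classify_targets(ids, ids, ids)
  g <- build_backbone(clique, cls2, "TF")
  core2 <- extract_core(g, seeds = c("k10", "k20"), size_target = 30)
  expect_equal(igraph::vcount(core2), 30L)
  picked <- setdiff(igraph::V(core2)$name, c("TF", "k10", "k20"))
  # every clique member has equal degree; ties resolve lexicographically
  expect_equal(sort(picked), head(setdiff(sort(ids), c("k10", "k20")), 27))

  # disconnected seed survives as an isolated node
  cls3 <- classify_targets(c("a1", "a2"), character(), c("a1", "a2", "a3"))
  g3 <- build_backbone(ppi_tbl("a1", "a3", 500), cls3, "TF")
  core3 <- extract_core(g3, seeds = c("a2"), size_target = 5)
  expect_true("a2" %in% igraph::V(core3)$name)
  expect_warning(extract_core(g3, seeds = c("zz"), size_target = 5), "absent")
})

test_that("category annotation validates labels and defaults to unannotated", {
  cls <- classify_targets(c("a"), c("b"), c("a", "b"))
  g <- build_backbone(ppi_tbl("a", "b", 500), cls, "TF")
  g0 <- annotate_categories(g, tibble::tibble(
    gene_id = character(), category = character()
  ))
  expect_true(all(grn_nodes(g0)$category == "unannotated"))
  g1 <- annotate_categories(g, tibble::tibble(
    gene_id = "a", category = "asexual development"
  ))
  expect_equal(grn_nodes(g1)$category[grn_nodes(g1)$name == "a"],
    "asexual development")
  # labels survive a GraphML round trip
  f <- tempfile(fileext = ".graphml")
  write_network(g1, f, "graphml")
  back <- read_network(f)
  expect_setequal(grn_nodes(back)$category, grn_nodes(g1)$category)
  expect_error(
    annotate_categories(g, tibble::tibble(gene_id = "a", category = "cooking")),
    "unknown category"
  )
})

test_that("graph construction is invariant to input row order", {
  set.seed(41)
  uni <- sprintf("g%02d", 1:25)
  cls <- classify_targets(sample(uni, 5), sample(uni, 8), uni)
  a <- sample(uni, 30, replace = TRUE)
  b <- sample(uni, 30, replace = TRUE)
  keep <- a != b
  edges <- dplyr::distinct(
    ppi_tbl(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]), 500)
  )
  g1 <- build_backbone(edges, cls, "TF")
  g2 <- build_backbone(edges[sample.int(nrow(edges)), ], cls, "TF")
  expect_equal(
    dplyr::arrange(tidy(g1), from, to, kind),
    dplyr::arrange(tidy(g2), from, to, kind)
  )
  expect_setequal(igraph::V(g1)$name, igraph::V(g2)$name)
})
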