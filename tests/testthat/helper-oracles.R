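# Independent brute-force oracles used to check the implementation paths.

# Quantile normalization by explicit sorting: per-rank cross-column means,
# with ties in a column replaced by the mean of the reference values of the
# tied positions. Written straight from the definition, element by element.
oracle_quantile_normalize <- function(m) {
  n <- nrow(m)
  sorted <- sapply(seq_len(ncol(m)), function(j) sort(m[, j]))
  ref <- rowMeans(sorted)
  out <- m
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    assigned <- numeric(n)
    assigned[order(col)] <- ref
    for (v in unique(col)) {
      idx <- which(col == v)
      assigned[idx] <- mean(assigned[idx])
    }
    out[, j] <- assigned
  }
  out
}

# All-pairs interval/summit overlap between peaks and promoter windows.
oracle_assign <- function(peaks, windows, mode = "interval") {
  bound <- character()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(windows))) {
      if (peaks$chrom[i] != windows$chrom[j]) next
      hit <- if (mode == "interval") {
        peaks$start[i] < windows$end[j] && windows$start[j] < peaks$end[i]
      } else {
        peaks$summit[i] >= windows$start[j] && peaks$summit[i] < windows$end[j]
      }
      if (hit) bound <- c(bound, windows$gene_id[j])
    }
  }
  sort(unique(bound))
}

# Depth-1 breadth-first expansion of a node set over an edge table.
oracle_bfs1 <- function(members, edges) {
  nbr <- c(
    edges$protein_b[edges$protein_a %in% members],
    edges$protein_a[edges$protein_b %in% members]
  )
  sort(union(members, nbr))
}

# Exact upper-tail hypergeometric P(X >= k) by enumerating all n-subsets of
# a universe of size N with K marked elements.
oracle_hyper_enum <- function(k, K, n, N) {
  subsets <- utils::combn(N, n)
  marked <- seq_len(K)
  overlap <- apply(subsets, 2, function(s) sum(s %in% marked))
  mean(overlap >= k)
}

# Naive sliding-window motif count on one strand.
oracle_scan <- function(seq, motif) {
  w <- nchar(motif)
  if (nchar(seq) < w) {
    return(0L)
  }
  sum(vapply(
    seq_len(nchar(seq) - w + 1L),
    function(i) substr(seq, i, i + w - 1L) == motif,
    logical(1)
  ))
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Small random gene/peak instance shared by the overlap property tests.
random_gene_table <- function(n, chroms = c("c1", "c2"), span = 2e5) {
  start <- sample.int(span, n) + 5000L
  strand <- sample(c("+", "-"), n, replace = TRUE)
  end <- start + sample(500:2000, n, replace = TRUE)
  tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = end, strand = strand,
    translation_start = ifelse(strand == "+", start, end - 1L)
  )
}

random_peak_table <- function(n, chroms = c("c1", "c2"), span = 2e5) {
  start <- sample.int(span + 10000L, n)
  width <- sample(50:800, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + width,
    name = sprintf("p%03d", seq_len(n)),
    score = NA_real_,
    summit = start + width %/% 2L
  )
}
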