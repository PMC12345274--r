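#' Promoter windows upstream of the translation start
#'
#' For each gene, the window of `window` bases strictly upstream of the
#' translation start site, in 0-based half-open coordinates:
#' `[ts - window, ts)` on the `+` strand and `[ts + 1, ts + 1 + window)` on
#' the `-` strand. The translation-start base itself is excluded. Windows
#' are clipped at position 0 and, when `seqlengths` is supplied, at the
#' chromosome end.
#'
#' @param genes a gene-model tibble from [read_annotation()].
#' @param window window length in bases (> 0).
#' @param seqlengths optional named vector of chromosome lengths for
#'   right-clipping.
#' @return A tibble `gene_id`, `chrom`, `start`, `end`, `strand` with one
#'   window per gene.
#' @export
promoter_windows <- function(genes, window = 1500, seqlengths = NULL) {
  if (window <= 0) abort("`window` must be positive")
  ts <- genes$translation_start
  start <- ifelse(genes$strand == "+", ts - window, ts + 1)
  end <- ifelse(genes$strand == "+", ts, ts + 1 + window)
  start <- pmax(start, 0)
  if (!is.null(seqlengths)) {
    lim <- unname(seqlengths[genes$chrom])
    end <- pmin(end, ifelse(is.na(lim), end, lim))
  }
  end <- pmax(end, start)
  tibble(
    gene_id = genes$gene_id, chrom = genes$chrom,
    start = as.integer(start), end = as.integer(end),
    strand = genes$strand
  )
}

#' Assign ChIP peaks to genes through promoter windows
#'
#' A gene is called bound when at least one peak hits its promoter window.
#' In the default `"interval"` mode any >= 1 base overlap between the peak
#' interval and the window counts; in `"summit"` mode the peak summit must
#' lie inside the window. One peak may bind several genes (every overlapped
#' promoter is assigned; there is no nearest-gene tie-break) and the result
#' is deterministic regardless of input row order. Peaks on chromosomes
#' absent from the annotation are skipped with a warning.
#'
#' @param peaks a peak tibble from [read_peaks()].
#' @param genes a gene-model tibble from [read_annotation()].
#' @param window promoter window length in bases.
#' @param mode `"interval"` (default) or `"summit"`.
#' @param seqlengths optional chromosome lengths, passed to
#'   [promoter_windows()].
#' @return A list with `bound` (sorted character vector of bound gene ids)
#'   and `assignments` (tibble `gene_id`, `peak`, `chrom`, `peak_start`,
#'   `peak_end`, `summit`).
#' @export
assign_peaks <- function(peaks, genes, window = 1500,
                         mode = c("interval", "summit"), seqlengths = NULL) {
  mode <- match.arg(mode)
  win <- promoter_windows(genes, window = window, seqlengths = seqlengths)
  unknown <- setdiff(unique(peaks$chrom), unique(genes$chrom))
  if (length(unknown) > 0) {
    warn(sprintf(
      "skipping %d peak(s) on chromosome(s) absent from the annotation: %s",
      sum(peaks$chrom %in% unknown), paste(unknown, collapse = ", ")
    ))
    peaks <- peaks[!peaks$chrom %in% unknown, , drop = FALSE]
  }
  empty <- tibble(
    gene_id = character(), peak = character(), chrom = character(),
    peak_start = integer(), peak_end = integer(), summit = integer()
  )
  win <- win[win$end > win$start, , drop = FALSE]
  if (nrow(peaks) == 0 || nrow(win) == 0) {
    return(list(bound = character(), assignments = empty))
  }
  win_gr <- GenomicRanges::GRanges(
    win$chrom, IRanges::IRanges(start = win$start + 1L, end = win$end)
  )
  peak_gr <- if (mode == "interval") {
    GenomicRanges::GRanges(
      peaks$chrom, IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
    )
  } else {
    GenomicRanges::GRanges(
      peaks$chrom,
      IRanges::IRanges(start = peaks$summit + 1L, width = 1L)
    )
  }
  hits <- GenomicRanges::findOverlaps(peak_gr, win_gr, minoverlap = 1L)
  if (length(hits) == 0) {
    return(list(bound = character(), assignments = empty))
  }
  assignments <- tibble(
    gene_id = win$gene_id[S4Vectors::subjectHits(hits)],
    peak = peaks$name[S4Vectors::queryHits(hits)],
    chrom = peaks$chrom[S4Vectors::queryHits(hits)],
    peak_start = peaks$start[S4Vectors::queryHits(hits)],
    peak_end = peaks$end[S4Vectors::queryHits(hits)],
    summit = peaks$summit[S4Vectors::queryHits(hits)]
  ) |>
    arrange(.data$gene_id, .data$peak, .data$peak_start)
  list(bound = sort(unique(assignments$gene_id)), assignments = assignments)
}

#' Classify regulator target genes
#'
#' Partitions the gene universe by combining the ChIP-bound (putative
#' direct) set with the differentially expressed set: `direct` is their
#' intersection, `indirect` the DEGs without promoter binding, and
#' `associated` their union (the regulator-associated genes), so that
#' |associated| = |putative_direct| + |degs| - |direct|.
#'
#' @param putative_direct character vector of ChIP-bound gene ids.
#' @param degs character vector of differentially expressed gene ids.
#' @param universe character vector of all annotated gene ids (or a single
#'   integer universe size when only counts and percentages are needed and
#'   both sets are known to be annotated).
#' @return A `target_classification` object: the five gene sets plus the
#'   universe size. [tidy()] gives per-set counts and percent-of-universe
#'   (one decimal); [glance()] a one-row summary.
#' @export
classify_targets <- function(putative_direct, degs, universe) {
  putative_direct <- check_character_set(putative_direct, "putative_direct")
  degs <- check_character_set(degs, "degs")
  if (is.numeric(universe) && length(universe) == 1L) {
    n_universe <- as.integer(universe)
    if (length(putative_direct) > n_universe || length(degs) > n_universe) {
      abort("gene sets larger than the stated universe size")
    }
  } else {
    universe <- check_character_set(universe, "universe")
    n_universe <- length(universe)
    for (nm in c("putative_direct", "degs")) {
      s <- get(nm)
      bad <- setdiff(s, universe)
      if (length(bad) > 0) {
        abort(sprintf(
          "`%s` contains %d gene(s) outside the universe, e.g. %s",
          nm, length(bad), paste(head(bad, 3), collapse = ", ")
        ))
      }
    }
  }
  direct <- intersect(putative_direct, degs)
  structure(
    list(
      putative_direct = putative_direct,
      degs = degs,
      direct = direct,
      indirect = setdiff(degs, putative_direct),
      associated = union(putative_direct, degs),
      n_universe = n_universe
    ),
    class = "target_classification"
  )
}

#' @export
print.target_classification <- function(x, ...) {
  cat("<target_classification>\n")
  print(tidy(x))
  invisible(x)
}

#' Count motif occurrences in promoter sequences
#'
#' Counts (possibly overlapping) occurrences of a motif and of its reverse
#' complement on the forward sequence, i.e. hits on both strands. Non-ACGT
#' characters never match and a message reports how many sequences contain
#' any.
#'
#' @param seqs promoter sequences: a [Biostrings::DNAStringSet], a named
#'   character vector, or the path to a FASTA file.
#' @param motif motif string over `{A, C, G, T}`.
#' @return A tibble `seq_id`, `length`, `forward`, `reverse`, `count`.
#' @export
scan_motif <- function(seqs, motif = "GATCT") {
  motif <- toupper(motif)
  if (!nzchar(motif)) abort("`motif` must be non-empty")
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs)) {
    seqs <- Biostrings::readDNAStringSet(seqs)
  }
  if (is.character(seqs)) {
    nms <- names(seqs) %||% paste0("seq_", seq_along(seqs))
    raw <- toupper(seqs)
    odd <- grepl("[^ACGT]", raw)
    if (any(odd)) {
      inform(sprintf(
        "%d sequence(s) contain non-ACGT characters; those positions never match",
        sum(odd)
      ))
      raw <- gsub("[^ACGT]", "N", raw)
    }
    seqs <- Biostrings::DNAStringSet(setNames(raw, nms))
  }
  fwd <- Biostrings::vcountPattern(motif, seqs)
  rev <- Biostrings::vcountPattern(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif))),
    seqs
  )
  tibble(
    seq_id = names(seqs) %||% paste0("seq_", seq_along(seqs)),
    length = Biostrings::width(seqs),
    forward = fwd,
    reverse = rev,
    count = fwd + rev
  )
}

#' Permutation test for motif enrichment in bound promoters
#'
#' The statistic is the difference in mean per-kilobase motif occurrence
#' rate between the bound and background groups. Significance comes from
#' shuffling group labels: with `r` permutation statistics at least as
#' large as the observed one, p = (r + 1) / (n + 1).
#'
#' @param bound,background [scan_motif()] tables (or tibbles with `count`
#'   and `length` columns) for the two promoter groups.
#' @param n_permutations number of label shuffles (a warning is issued
#'   below 100).
#' @param seed optional integer seed for the shuffles.
#' @return A `motif_enrichment` list: `statistic` (per-kb rate difference,
#'   bound minus background), `p_value`, `n_permutations`, group sizes.
#' @export
motif_enrichment <- function(bound, background, n_permutations = 1000,
                             seed = NULL) {
  if (nrow(bound) == 0 || nrow(background) == 0) {
    abort("both promoter groups must be non-empty")
  }
  if (n_permutations < 100) {
    warn("fewer than 100 permutations gives a coarse p-value")
  }
  if (!is.null(seed)) set.seed(seed)
  rate <- function(x) x$count / (x$length / 1000)
  rb <- rate(bound)
  rg <- rate(background)
  obs <- mean(rb) - mean(rg)
  pooled <- c(rb, rg)
  nb <- length(rb)
  perm <- vapply(seq_len(n_permutations), function(i) {
    idx <- sample.int(length(pooled), nb)
    mean(pooled[idx]) - mean(pooled[-idx])
  }, double(1))
  r <- sum(perm >= obs)
  structure(
    list(
      statistic = obs,
      p_value = (r + 1) / (n_permutations + 1),
      n_permutations = n_permutations,
      n_bound = nb,
      n_background = length(rg)
    ),
    class = "motif_enrichment"
  )
}

#' @export
print.motif_enrichment <- function(x, ...) {
  cat(sprintf(
    "<motif_enrichment> rate difference %.3f occ/kb (bound - background), p = %.4g [%d permutations]\n",
    x$statistic, x$p_value, x$n_permutations
  ))
  invisible(x)
}
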