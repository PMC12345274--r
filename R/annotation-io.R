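#' Read gene models from a GFF3 annotation
#'
#' Parses `gene` features (and their CDS children, through one level of
#' `mRNA`/transcript nesting) into a gene-model table. GFF3 1-based inclusive
#' coordinates are converted to the package-wide 0-based half-open
#' convention on read. The translation start is the first coding base in
#' transcription order (leftmost CDS base on `+`, rightmost on `-`); genes
#' without CDS children fall back to their 5' end, which equals the
#' translation start for the single-exon gene models the synthetic generator
#' emits.
#'
#' @param path path to a GFF3 file.
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand` and `translation_start` (0-based
#'   position of the first coding base), in file order.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  empty <- tibble(
    gene_id = character(), chrom = character(),
    start = integer(), end = integer(),
    strand = character(), translation_start = integer()
  )
  if (length(gr) == 0) {
    return(empty)
  }
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  if (length(genes) == 0) {
    return(empty)
  }
  ids <- as.character(genes$ID)
  if (anyNA(ids)) abort("gene feature without an ID attribute")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate gene ID(s): %s", paste(dup, collapse = ", ")))
  }
  strand <- as.character(GenomicRanges::strand(genes))
  if (any(strand == "*")) {
    abort(sprintf(
      "gene(s) without strand: %s",
      paste(ids[strand == "*"], collapse = ", ")
    ))
  }

  # resolve CDS -> gene through an optional transcript level
  parent_of <- function(x) {
    p <- x$Parent
    vapply(seq_along(x), function(i) {
      pi <- p[[i]]
      if (length(pi) == 0) NA_character_ else as.character(pi[[1L]])
    }, character(1))
  }
  tx <- gr[type %in% c("mRNA", "transcript")]
  tx_gene <- setNames(parent_of(tx), as.character(tx$ID))
  cds <- gr[type == "CDS"]
  ts <- rep(NA_integer_, length(genes))
  names(ts) <- ids
  if (length(cds) > 0) {
    cds_parent <- parent_of(cds)
    cds_gene <- ifelse(cds_parent %in% names(tx_gene),
      unname(tx_gene[cds_parent]), cds_parent
    )
    keep <- cds_gene %in% ids
    cds <- cds[keep]
    cds_gene <- cds_gene[keep]
    if (length(cds) > 0) {
      cds_tbl <- tibble(
        gene_id = cds_gene,
        cds_start = GenomicRanges::start(cds), # 1-based
        cds_end = GenomicRanges::end(cds)
      )
      first <- cds_tbl |>
        group_by(.data$gene_id) |>
        summarise(
          leftmost = min(.data$cds_start),
          rightmost = max(.data$cds_end),
          .groups = "drop"
        )
      gene_strand <- setNames(strand, ids)
      ts_val <- ifelse(gene_strand[first$gene_id] == "+",
        first$leftmost - 1L, # first coding base, 0-based
        first$rightmost - 1L
      )
      ts[first$gene_id] <- as.integer(ts_val)
    }
  }
  start0 <- GenomicRanges::start(genes) - 1L
  end0 <- GenomicRanges::end(genes)
  # fall back to the gene 5' end when no CDS is annotated
  fallback <- ifelse(strand == "+", start0, end0 - 1L)
  ts[is.na(ts)] <- as.integer(fallback[is.na(ts)])
  tibble(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = as.integer(start0),
    end = as.integer(end0),
    strand = strand,
    translation_start = as.integer(unname(ts[ids]))
  )
}

#' Write gene models to GFF3
#'
#' Emits one `gene` feature per row plus one CDS child anchored at the
#' translation start, so that [read_annotation()] round-trips the
#' `translation_start` column exactly. Internal 0-based half-open
#' coordinates are converted back to GFF3 1-based inclusive on write.
#'
#' @param genes a gene-model tibble as returned by [read_annotation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(genes, path) {
  if (nrow(genes) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gene_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand,
    type = "gene",
    ID = genes$gene_id
  )
  # CDS spanning from the translation start to the gene 3' end
  cds_start1 <- ifelse(genes$strand == "+", genes$translation_start + 1L,
    genes$start + 1L
  )
  cds_end1 <- ifelse(genes$strand == "+", genes$end,
    genes$translation_start + 1L
  )
  cds_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = cds_start1, end = cds_end1),
    strand = genes$strand,
    type = "CDS",
    phase = 0L,
    ID = paste0(genes$gene_id, ".cds"),
    Parent = as.character(genes$gene_id)
  )
  gr <- c(gene_gr, cds_gr)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read ChIP peaks from a BED or narrowPeak file
#'
#' Accepts BED3 through BED6 and ENCODE narrowPeak (10 columns); rows with
#' different column counts may be mixed. BED 0-based half-open coordinates
#' pass through unchanged. The summit is `start + offset` when a narrowPeak
#' summit-offset column is present and non-negative, otherwise the interval
#' midpoint (floor).
#'
#' @param path path to a tab-separated peak file; `track`, `browser` and `#`
#'   comment lines are skipped.
#' @return A tibble with `chrom`, `start`, `end`, `name`, `score`, `summit`
#'   in file order. Missing names default to `peak_<row>`.
#' @export
read_peaks <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      name = character(), score = double(), summit = integer()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  parse_row <- function(f, ln, idx) {
    if (length(f) < 3L) {
      abort(sprintf("line %d: expected at least 3 tab-separated columns", ln))
    }
    start <- suppressWarnings(as.integer(f[[2L]]))
    end <- suppressWarnings(as.integer(f[[3L]]))
    if (is.na(start) || is.na(end)) {
      abort(sprintf("line %d: non-numeric start/end", ln))
    }
    if (start >= end) {
      abort(sprintf("line %d: start (%d) >= end (%d)", ln, start, end))
    }
    name <- if (length(f) >= 4L && nzchar(f[[4L]]) && f[[4L]] != ".") {
      f[[4L]]
    } else {
      paste0("peak_", idx)
    }
    score <- if (length(f) >= 5L) suppressWarnings(as.numeric(f[[5L]])) else NA_real_
    offset <- if (length(f) >= 10L) suppressWarnings(as.integer(f[[10L]])) else NA_integer_
    summit <- if (!is.na(offset) && offset >= 0L) {
      start + offset
    } else {
      start + (end - start) %/% 2L
    }
    tibble(
      chrom = f[[1L]], start = start, end = end,
      name = name, score = score, summit = summit
    )
  }
  purrr::pmap(
    list(fields, line_no, seq_along(fields)),
    parse_row
  ) |> bind_rows()
}

#' Write peaks as narrowPeak
#'
#' Always emits the 10-column narrowPeak layout with the summit encoded as
#' an offset from `start`, so [read_peaks()] round-trips coordinates and
#' summits exactly.
#'
#' @param peaks a peak tibble as returned by [read_peaks()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  score <- ifelse(is.na(peaks$score), 0, peaks$score)
  out <- data.frame(
    peaks$chrom, peaks$start, peaks$end, peaks$name, score,
    ".", 0, -1, -1, peaks$summit - peaks$start
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
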