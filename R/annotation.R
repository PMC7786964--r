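#' Transcript annotation container
#'
#' An `lnc_annotation` bundles a set of exon-structured transcript
#' models with an interval index. Coordinates are 1-based inclusive
#' genomic positions throughout (GTF convention); BED-style input is
#' converted at the reading boundary.
#'
#' @param exons data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand` (one row per exon). Optionally a
#'   `biotype` column (per transcript; first value per transcript wins).
#' @param chrom_sizes optional named vector of chromosome lengths (bp);
#'   exons are validated against it when present.
#' @return an object of class `lnc_annotation` with elements
#'   `exons` (per-exon table, sorted by transcript then start),
#'   `transcripts` (one row per transcript: span, exon count, exonic
#'   length, biotype) and `chrom_sizes`.
#' @export
annotation <- function(exons, chrom_sizes = NULL) {
  needed <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(needed, names(exons))
  if (length(missing_cols))
    stop("exon table lacks columns: ", paste(missing_cols, collapse = ", "))
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  if (nrow(exons) == 0L) {
    tx <- data.frame(transcript_id = character(), gene_id = character(),
                     chrom = character(), strand = character(),
                     start = integer(), end = integer(),
                     n_exons = integer(), exonic_length = integer(),
                     biotype = character(), stringsAsFactors = FALSE)
    return(structure(list(exons = exons, transcripts = tx,
                          chrom_sizes = chrom_sizes),
                     class = "lnc_annotation"))
  }
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (anyNA(exons$start) || anyNA(exons$end))
    stop("non-numeric exon coordinates")
  if (any(exons$start > exons$end)) stop("exon with start > end")
  if (any(exons$start < 1L)) stop("exon coordinates must be >= 1")
  if (!all(exons$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  if (!is.null(chrom_sizes)) {
    sz <- chrom_sizes[exons$chrom]
    bad <- which(!is.na(sz) & exons$end > sz)
    if (length(bad))
      stop("exon beyond chromosome end for transcript ",
           exons$transcript_id[bad[1]])
  }
  if (!"biotype" %in% names(exons)) exons$biotype <- NA_character_
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL

  # per-transcript consistency: single chrom/strand, non-overlapping exons
  sp <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (idx in sp) {
    if (length(unique(exons$chrom[idx])) != 1L ||
        length(unique(exons$strand[idx])) != 1L)
      stop("transcript ", exons$transcript_id[idx[1]],
           " spans multiple chromosomes or strands")
    if (length(idx) > 1L) {
      s <- exons$start[idx]; e <- exons$end[idx]
      if (any(s[-1] <= e[-length(e)]))
        stop("overlapping exons in transcript ", exons$transcript_id[idx[1]])
    }
  }
  first <- vapply(sp, `[`, integer(1), 1L)
  tx <- data.frame(
    transcript_id = exons$transcript_id[first],
    gene_id = exons$gene_id[first],
    chrom = exons$chrom[first],
    strand = exons$strand[first],
    start = vapply(sp, function(i) min(exons$start[i]), integer(1)),
    end = vapply(sp, function(i) max(exons$end[i]), integer(1)),
    n_exons = lengths(sp),
    exonic_length = vapply(sp, function(i)
      sum(exons$end[i] - exons$start[i] + 1L), integer(1)),
    biotype = exons$biotype[first],
    stringsAsFactors = FALSE)
  rownames(tx) <- NULL
  structure(list(exons = exons, transcripts = tx, chrom_sizes = chrom_sizes),
            class = "lnc_annotation")
}

#' @export
print.lnc_annotation <- function(x, ...) {
  cat(sprintf("<lnc_annotation> %d transcripts / %d loci on %d chromosome(s)\n",
              nrow(x$transcripts),
              length(unique(x$transcripts$gene_id)),
              length(unique(x$transcripts$chrom))))
  invisible(x)
}

#' Number of transcripts in an annotation
#' @param x an `lnc_annotation`.
#' @export
n_transcripts <- function(x) nrow(x$transcripts)

#' Restrict an annotation to a set of transcripts
#' @param x an `lnc_annotation`.
#' @param ids transcript identifiers to keep.
#' @return an `lnc_annotation` holding only `ids`.
#' @export
subset_annotation <- function(x, ids) {
  annotation(x$exons[x$exons$transcript_id %in% ids, , drop = FALSE],
             chrom_sizes = x$chrom_sizes)
}

#' Intron intervals of every multi-exon transcript
#'
#' @param x an `lnc_annotation`.
#' @return data.frame `transcript_id`, `chrom`, `start`, `end`, `strand`
#'   with one row per intron (the 1-based inclusive gaps between
#'   consecutive exons); zero rows when all transcripts are monoexonic.
#' @export
introns <- function(x) {
  ex <- x$exons
  sp <- split(seq_len(nrow(ex)), ex$transcript_id)
  out <- lapply(sp, function(i) {
    if (length(i) < 2L) return(NULL)
    data.frame(transcript_id = ex$transcript_id[i[1]],
               chrom = ex$chrom[i[1]],
               start = ex$end[i[-length(i)]] + 1L,
               end = ex$start[i[-1]] - 1L,
               strand = ex$strand[i[1]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(transcript_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# findOverlaps emits a warning when query and subject share no
# sequence levels (features on different chromosomes); here that is an
# ordinary no-overlap answer
quiet_overlaps <- function(...) {
  withCallingHandlers(
    GenomicRanges::findOverlaps(...),
    warning = function(w) {
      if (grepl("sequence levels in common", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

# GRanges views used by the interval machinery ------------------------------

exons_gr <- function(x) {
  ex <- x$exons
  GenomicRanges::GRanges(ex$chrom,
                         IRanges::IRanges(ex$start, ex$end),
                         strand = ex$strand,
                         transcript_id = ex$transcript_id,
                         gene_id = ex$gene_id)
}

spans_gr <- function(x) {
  tx <- x$transcripts
  GenomicRanges::GRanges(tx$chrom,
                         IRanges::IRanges(tx$start, tx$end),
                         strand = tx$strand,
                         transcript_id = tx$transcript_id,
                         gene_id = tx$gene_id)
}

#' Transcripts whose span intersects a genomic interval
#'
#' Interval-index lookup: returns exactly the transcripts whose span
#' `[min exon start, max exon end]` intersects the query.
#'
#' @param x an `lnc_annotation`.
#' @param chrom chromosome name.
#' @param start,end query interval, 1-based inclusive.
#' @return character vector of transcript ids.
#' @export
query_overlaps <- function(x, chrom, start, end) {
  if (nrow(x$transcripts) == 0L) return(character())
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  hits <- quiet_overlaps(q, spans_gr(x), ignore.strand = TRUE)
  x$transcripts$transcript_id[unique(S4Vectors::subjectHits(hits))]
}
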