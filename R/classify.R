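#' Class codes
#'
#' Transcripts are classified against the reference annotation with a
#' reduced, strand-aware version of the gffcompare code set:
#' \describe{
#'   \item{`"sense"`}{any exonic overlap with a reference transcript on
#'     the same strand (collapses '=', 'j', 'c', 'o', ...); excluded
#'     from lncRNA candidacy}
#'   \item{`"x"`}{exonic overlap with a reference transcript on the
#'     opposite strand only (antisense)}
#'   \item{`"i"`}{span fully contained within a single reference
#'     intron, no exonic overlap anywhere}
#'   \item{`"u"`}{intergenic: no exonic overlap and no intron
#'     containment}
#' }
#' Only `"u"`, `"i"` and `"x"` proceed to lncRNA candidacy.
#'
#' @name class_codes
NULL

CLASS_CODES <- c("sense", "x", "i", "u")

# exon rows of one transcript
transcript_exons <- function(x, id) {
  ex <- x$exons[x$exons$transcript_id == id, , drop = FALSE]
  if (!nrow(ex)) stop("unknown transcript: ", id)
  ex
}

#' Total exonic overlap between two transcript models
#'
#' @param a,b per-exon data.frames (columns `chrom`, `start`, `end`),
#'   e.g. rows of `annotation$exons` for one transcript each.
#' @return shared base pairs between any exon of `a` and any exon of
#'   `b`; 0 when they are disjoint or on different chromosomes.
#' @export
exonic_overlap_bp <- function(a, b) {
  if (a$chrom[1] != b$chrom[1]) return(0L)
  total <- 0L
  for (i in seq_len(nrow(a))) {
    ov <- pmin(a$end[i], b$end) - pmax(a$start[i], b$start) + 1L
    total <- total + sum(pmax(0L, ov))
  }
  total
}

#' Is a transcript fully contained in one intron of a reference model?
#'
#' @param t,ref per-exon data.frames as in [exonic_overlap_bp()].
#' @return TRUE iff the span of `t` lies entirely within a single
#'   intron interval of `ref`; FALSE for a monoexonic `ref`.
#' @export
intron_containment <- function(t, ref) {
  if (t$chrom[1] != ref$chrom[1]) return(FALSE)
  if (nrow(ref) < 2L) return(FALSE)
  ref <- ref[order(ref$start), , drop = FALSE]
  ints <- cbind(ref$end[-nrow(ref)] + 1L, ref$start[-1] - 1L)
  span <- c(min(t$start), max(t$end))
  any(ints[, 1] <= span[1] & span[2] <= ints[, 2])
}

#' Classify every transcript of an assembly against a reference
#'
#' Precedence per transcript: same-strand exonic overlap with any
#' reference transcript -> `"sense"`; else opposite-strand exonic
#' overlap -> `"x"`; else containment within a reference intron (either
#' strand) -> `"i"`; else `"u"`. Unstranded transcripts cannot be
#' classified (the codes are strand-defined) and are dropped with a
#' warning.
#'
#' @param novel,reference [annotation()] objects.
#' @return data.frame `transcript_id`, `code`; excluded unstranded ids
#'   are attached as `attr(, "unstranded")`.
#' @export
classify_transcripts <- function(novel, reference) {
  tx <- novel$transcripts
  unstranded <- tx$transcript_id[tx$strand == "."]
  if (length(unstranded))
    warning(length(unstranded),
            " unstranded transcript(s) excluded from classification")
  tx <- tx[tx$strand != ".", , drop = FALSE]
  if (!nrow(tx))
    return(structure(data.frame(transcript_id = character(),
                                code = character()),
                     unstranded = unstranded))
  code <- stats::setNames(rep(NA_character_, nrow(tx)), tx$transcript_id)

  nov <- subset_annotation(novel, tx$transcript_id)
  nex <- exons_gr(nov)
  if (nrow(reference$exons)) {
    rex <- exons_gr(reference)
    hits <- quiet_overlaps(nex, rex, ignore.strand = TRUE)
    if (length(hits)) {
      ntid <- nex$transcript_id[S4Vectors::queryHits(hits)]
      same <- as.character(GenomicRanges::strand(nex))[S4Vectors::queryHits(hits)] ==
        as.character(GenomicRanges::strand(rex))[S4Vectors::subjectHits(hits)]
      code[unique(ntid[same])] <- "sense"
      xids <- setdiff(unique(ntid[!same]), unique(ntid[same]))
      code[xids] <- "x"
    }
  }

  # intron containment, either strand, only for exon-overlap-free transcripts
  open <- names(code)[is.na(code)]
  if (length(open) && nrow(reference$exons)) {
    ri <- introns(reference)
    if (nrow(ri)) {
      igr <- GenomicRanges::GRanges(ri$chrom, IRanges::IRanges(ri$start, ri$end))
      otx <- tx[tx$transcript_id %in% open, , drop = FALSE]
      sgr <- GenomicRanges::GRanges(otx$chrom,
                                    IRanges::IRanges(otx$start, otx$end))
      w <- quiet_overlaps(sgr, igr, type = "within",
                          ignore.strand = TRUE)
      code[otx$transcript_id[unique(S4Vectors::queryHits(w))]] <- "i"
    }
  }
  code[is.na(code)] <- "u"
  structure(data.frame(transcript_id = names(code), code = unname(code),
                       stringsAsFactors = FALSE),
            unstranded = unstranded)
}

#' Class code of a single transcript
#'
#' @param novel an [annotation()] holding exactly one transcript (or
#'   more; each is classified and the first returned).
#' @param reference reference [annotation()].
#' @return a code from [class_codes]. Unstranded input is an error.
#' @export
assign_class_code <- function(novel, reference) {
  if (any(novel$transcripts$strand == "."))
    stop("cannot classify an unstranded transcript")
  classify_transcripts(novel, reference)$code[1]
}

#' Map retained class codes to lncRNA classes
#'
#' @param code character vector of codes `"u"`, `"i"`, `"x"`.
#' @return `"lincRNA"`, `"ilncRNA"` or `"lncNAT"` respectively.
#' @export
lncrna_class <- function(code) {
  map <- c(u = "lincRNA", i = "ilncRNA", x = "lncNAT")
  bad <- setdiff(unique(code), names(map))
  if (length(bad)) stop("no lncRNA class for code: ", bad[1])
  unname(map[code])
}
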