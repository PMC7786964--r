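#' Spliced transcript sequence
#'
#' Concatenates exon sequences 5'->3'; minus-strand transcripts are
#' reverse-complemented. `N` bases are preserved.
#'
#' @param x an [annotation()] object.
#' @param id transcript identifier.
#' @param genome `DNAStringSet` from [read_genome_fasta()].
#' @return character scalar, the sense-strand spliced sequence.
#' @export
spliced_sequence <- function(x, id, genome) {
  ex <- transcript_exons(x, id)
  chrom <- ex$chrom[1]
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  len <- length(genome[[chrom]])
  if (any(ex$end > len) || any(ex$start < 1L))
    stop("exon out of chromosome bounds for transcript ", id)
  pieces <- Biostrings::extractAt(
    genome[[chrom]], IRanges::IRanges(ex$start, ex$end))
  s <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
  if (ex$strand[1] == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Length of the longest open reading frame
#'
#' Scans the three forward frames of the sense-strand spliced sequence
#' for the longest reading frame starting at `ATG`. The length includes
#' the stop codon when one is present; an ORF without an in-frame stop
#' extends to the last complete codon and still counts. Codons
#' containing `N` are neither starts nor stops.
#'
#' @param seq nucleotide string over `A`,`C`,`G`,`T`,`N`.
#' @return ORF length in nt; 0 when the sequence has no `ATG`.
#' @export
longest_orf <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 3L) return(0L)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (f in 0:2) {
    starts_at <- seq.int(f + 1L, n - 2L, by = 3L)
    if (f + 3L > n) next
    cod <- substring(seq, starts_at, starts_at + 2L)
    ncod <- length(cod)
    atg <- which(cod == "ATG")
    if (!length(atg)) next
    stp <- which(cod %in% stops)
    # index of the first stop codon at or after each ATG
    pos <- findInterval(atg - 0.5, stp) + 1L
    len <- ifelse(pos <= length(stp),
                  (stp[pos] - atg + 1L) * 3L,
                  (ncod - atg + 1L) * 3L)
    best <- max(best, len)
  }
  as.integer(best)
}
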