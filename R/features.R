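#' Size statistics of a transcript set
#'
#' @param x an [annotation()] object.
#' @return list with vectors `transcript_length` (spliced exonic
#'   length per transcript), `exon_count`, pooled `exon_length` and
#'   `intron_length`, and a `summary` data.frame of medians and
#'   quartiles.
#' @export
size_stats <- function(x) {
  tx <- x$transcripts
  ex <- x$exons
  il <- introns(x)
  vecs <- list(transcript_length = tx$exonic_length,
               exon_count = tx$n_exons,
               exon_length = ex$end - ex$start + 1L,
               intron_length = if (nrow(il)) il$end - il$start + 1L
                               else integer())
  qs <- t(vapply(vecs, function(v) {
    if (!length(v)) return(c(NA_real_, NA_real_, NA_real_))
    stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  }, numeric(3)))
  summary <- data.frame(metric = names(vecs), q1 = qs[, 1],
                        median = qs[, 2], q3 = qs[, 3],
                        n = lengths(vecs), row.names = NULL)
  c(vecs, list(summary = summary))
}

#' GC content of nucleotide sequences
#'
#' @param seq character vector of nucleotide strings.
#' @return percentage `100 * (G + C) / (A + C + G + T)` per sequence;
#'   `N` and other ambiguity codes are excluded from the denominator,
#'   and a sequence with no unambiguous bases gives NA.
#' @export
gc_content <- function(seq) {
  vapply(toupper(seq), function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    n_gc <- sum(b %in% c("G", "C"))
    n_ok <- sum(b %in% c("A", "C", "G", "T"))
    if (n_ok == 0) NA_real_ else 100 * n_gc / n_ok
  }, numeric(1), USE.NAMES = FALSE)
}

#' Base composition around splice sites
#'
#' For every intron of every multi-exon transcript, tallies the
#' strand-corrected bases at the donor site (last `flank` nt of the
#' upstream exon + first `flank` nt of the intron) and the acceptor
#' site (last `flank` nt of the intron + first `flank` nt of the
#' downstream exon). Introns shorter than `flank` contribute only their
#' available intronic positions; windows running off the chromosome are
#' skipped.
#'
#' @param x an [annotation()] object (multi-exon transcripts used).
#' @param genome `DNAStringSet`.
#' @param flank positions tallied on each side of the junctions.
#' @return list `donor` and `acceptor` (4 x 2*flank frequency matrices,
#'   columns sum to 1 where data exist), `canonical_fraction` (introns
#'   with GT...AG) and `n_introns`.
#' @export
splice_site_context <- function(x, genome, flank = 10) {
  il <- introns(x)
  sizes <- genome_sizes(genome)
  bases <- c("A", "C", "G", "T")
  donor <- acceptor <- matrix(0, 4, 2 * flank,
                              dimnames = list(bases, c(
                                paste0("E", -flank:-1),
                                paste0("I", 1:flank))))
  colnames(acceptor) <- c(paste0("I", -flank:-1), paste0("A", 1:flank))
  canonical <- 0L
  n <- 0L
  add_window <- function(mat, s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    for (j in seq_along(b)) {
      if (b[j] %in% bases) mat[b[j], j] <- mat[b[j], j] + 1
    }
    mat
  }
  for (k in seq_len(nrow(il))) {
    chrom <- il$chrom[k]
    lo <- il$start[k] - flank
    hi <- il$end[k] + flank
    if (lo < 1L || hi > sizes[chrom]) next
    L <- il$end[k] - il$start[k] + 1L
    region <- as.character(Biostrings::extractAt(
      genome[[chrom]], IRanges::IRanges(lo, hi))[[1]])
    if (il$strand[k] == "-")
      region <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(region)))
    # region is now sense-oriented: flank exonic, intron (L), flank exonic
    ex5 <- substr(region, 1, flank)
    intr <- substr(region, flank + 1, flank + L)
    ex3 <- substr(region, flank + L + 1, 2 * flank + L)
    di <- min(flank, L)
    donor <- add_window(donor, paste0(ex5, substr(intr, 1, di)))
    acc_intr <- substr(intr, L - di + 1, L)
    # right-align the intronic side of the acceptor window
    pad <- strrep("N", flank - di)
    acceptor <- add_window(acceptor, paste0(pad, acc_intr, ex3))
    if (substr(intr, 1, 2) == "GT" && substr(intr, L - 1, L) == "AG")
      canonical <- canonical + 1L
    n <- n + 1L
  }
  norm <- function(m) {
    cs <- colSums(m)
    m[, cs > 0] <- sweep(m[, cs > 0, drop = FALSE], 2, cs[cs > 0], "/")
    m
  }
  list(donor = norm(donor), acceptor = norm(acceptor),
       canonical_fraction = if (n) canonical / n else NA_real_,
       n_introns = n)
}

# per-feature TE overlap hits (exon or span mode)
te_hits <- function(x, te, mode = c("exon", "span")) {
  mode <- match.arg(mode)
  if (!nrow(te) || !nrow(x$transcripts))
    return(data.frame(feature_id = character(), te_index = integer(),
                      te_class = character()))
  gr <- if (mode == "exon") exons_gr(x) else spans_gr(x)
  tgr <- GenomicRanges::GRanges(te$chrom, IRanges::IRanges(te$start, te$end))
  h <- quiet_overlaps(gr, tgr, ignore.strand = TRUE)
  df <- unique(data.frame(
    feature_id = gr$transcript_id[S4Vectors::queryHits(h)],
    te_index = S4Vectors::subjectHits(h), stringsAsFactors = FALSE))
  df$te_class <- te$te_class[df$te_index]
  df
}

#' Transposable-element overlap of two feature classes
#'
#' A feature overlaps a TE iff any exon shares at least 1 bp with any
#' TE record (`mode = "span"` uses the transcript span instead). The
#' two feature sets are compared with a two-sided Fisher's exact test
#' on the overlap / non-overlap counts.
#'
#' @param a,b [annotation()] objects (e.g. lncRNAs and PCGs).
#' @param te TE track from [read_te_track()].
#' @param mode overlap mode, `"exon"` (default) or `"span"`.
#' @return list with `flags_a`, `flags_b` (named logicals), `hits_a`,
#'   `hits_b` (per-record overlap pairs with TE class labels), `table`
#'   (2x2 counts) and `test` (an `lnc_test`; p = NA when the TE track
#'   is empty).
#' @export
te_overlap <- function(a, b, te, mode = c("exon", "span")) {
  mode <- match.arg(mode)
  ha <- te_hits(a, te, mode)
  hb <- te_hits(b, te, mode)
  fa <- stats::setNames(a$transcripts$transcript_id %in% ha$feature_id,
                        a$transcripts$transcript_id)
  fb <- stats::setNames(b$transcripts$transcript_id %in% hb$feature_id,
                        b$transcripts$transcript_id)
  tab <- matrix(c(sum(fa), sum(!fa), sum(fb), sum(!fb)), 2,
                dimnames = list(c("overlap", "no_overlap"), c("a", "b")))
  test <- if (nrow(te)) fisher_exact_2x2(tab)
          else lnc_test(NA_real_, NA_real_, "Fisher's exact test (skipped)")
  list(flags_a = fa, flags_b = fb, hits_a = ha, hits_b = hb,
       table = tab, test = test)
}

#' TE class composition of overlap hits
#'
#' Each (feature, TE record) overlap contributes the TE record's class
#' once, so the tallies count overlapped TE records, not features.
#'
#' @param hits data.frame of overlap pairs (`hits_a`/`hits_b` from
#'   [te_overlap()]).
#' @return data.frame `te_class`, `n`, `pct` (shares sum to 100).
#' @export
te_class_composition <- function(hits) {
  if (!nrow(hits))
    return(data.frame(te_class = character(), n = integer(),
                      pct = numeric()))
  tab <- table(hits$te_class)
  data.frame(te_class = names(tab), n = as.integer(tab),
             pct = round_half_up(100 * as.integer(tab) / sum(tab), 2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Chromosome distribution of lncRNAs
#'
#' Counts lncRNA transcripts per chromosome and correlates the counts
#' with chromosome size and with the per-chromosome PCG count (Pearson,
#' two-sided p from the t distribution). Correlations are skipped (NA)
#' with fewer than 3 chromosomes.
#'
#' @param lnc lncRNA [annotation()].
#' @param reference PCG reference [annotation()]; its `chrom_sizes`
#'   (or `chrom_sizes` of `lnc`) must be set.
#' @return list `counts` (data.frame `chrom`, `n_lnc`, `n_pcg`,
#'   `size`), `r_size`, `p_size`, `r_pcg`, `p_pcg`.
#' @export
chromosome_distribution <- function(lnc, reference) {
  sizes <- reference$chrom_sizes %||% lnc$chrom_sizes
  if (is.null(sizes)) stop("chromosome sizes unknown")
  chroms <- names(sizes)
  n_lnc <- vapply(chroms, function(c)
    sum(lnc$transcripts$chrom == c), integer(1))
  n_pcg <- vapply(chroms, function(c)
    length(unique(reference$transcripts$gene_id[
      reference$transcripts$chrom == c])), integer(1))
  counts <- data.frame(chrom = chroms, n_lnc = n_lnc, n_pcg = n_pcg,
                       size = as.numeric(sizes), row.names = NULL)
  out <- list(counts = counts, r_size = NA_real_, p_size = NA_real_,
              r_pcg = NA_real_, p_pcg = NA_real_)
  if (length(chroms) >= 3) {
    safe_cor <- function(x, y)
      tryCatch(pearson_cor(x, y),
               error = function(e) list(r = NA_real_, p_value = NA_real_))
    cs <- safe_cor(counts$n_lnc, counts$size)
    out$r_size <- cs$r; out$p_size <- cs$p_value
    cp <- safe_cor(counts$n_lnc, counts$n_pcg)
    out$r_pcg <- cp$r; out$p_pcg <- cp$p_value
  }
  out
}
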