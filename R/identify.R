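#' Filtering thresholds for lncRNA identification
#'
#' Defaults follow the standard stringent cascade: candidates must be
#' at least 200 nt with at least two exons, lack an ORF of 300 nt or
#' more, carry no external coding evidence (CPC/CNCI predictions,
#' BLASTX vs SwissProt and Pfam searches, all produced externally at
#' E = 1e-3), and reach RPKM >= 1.0 in at least one sample.
#'
#' @param min_length_nt minimum spliced transcript length (nt).
#' @param min_exons minimum exon count.
#' @param max_orf_nt ORFs of this size or longer disqualify.
#' @param min_rpkm_max minimum of the per-transcript maximum RPKM over
#'   all samples.
#' @return list of thresholds used by [apply_filter_cascade()].
#' @export
filter_criteria <- function(min_length_nt = 200, min_exons = 2,
                            max_orf_nt = 300, min_rpkm_max = 1.0) {
  stopifnot(min_length_nt > 0, min_exons > 0, max_orf_nt > 0,
            min_rpkm_max > 0)
  list(min_length_nt = min_length_nt, min_exons = min_exons,
       max_orf_nt = max_orf_nt, min_rpkm_max = min_rpkm_max)
}

#' Apply the lncRNA filter cascade
#'
#' Takes transcripts already restricted to the retained class codes
#' (`u`/`i`/`x`) and applies, in order: (a) length >= 200 nt and >= 2
#' exons; (b) not predicted coding by CPC and not by CNCI; (c) longest
#' ORF < 300 nt; (d) no BLASTX hit; (e) no Pfam hit; (f) RPKM_max >=
#' 1.0. All six predicates are evaluated for every input transcript, so
#' the survivor set is invariant to the order of (b)-(e); the report
#' counts survivors stage by stage in the order above.
#'
#' @param x [annotation()] of candidate transcripts.
#' @param codes data.frame `transcript_id`, `code` from
#'   [classify_transcripts()], restricted to codes u/i/x.
#' @param genome `DNAStringSet` for ORF scanning.
#' @param evidence coding-evidence data.frame
#'   ([read_evidence_table()]); transcripts absent from it count as
#'   evidence-free. `NULL` means no transcript has evidence.
#' @param expr an [expression_table()]; transcripts absent from it get
#'   `rpkm_max = 0` (they fail criterion f) with a warning.
#' @param criteria a [filter_criteria()] list.
#' @return list with
#'   \describe{
#'     \item{records}{data.frame of survivors: `transcript_id`,
#'       `gene_id`, `code`, `class`, `rpkm_max` and per-criterion
#'       `pass_*` flags}
#'     \item{provenance}{the same flags for every input transcript}
#'     \item{report}{data.frame `stage`, `n_input`, `n_surviving`}
#'     \item{lncrna}{[annotation()] of survivors with `biotype` set to
#'       the lncRNA class}
#'   }
#' @export
apply_filter_cascade <- function(x, codes, genome, evidence = NULL,
                                 expr = NULL,
                                 criteria = filter_criteria()) {
  bad <- setdiff(unique(codes$code), c("u", "i", "x"))
  if (length(bad))
    stop("filter cascade expects codes u/i/x only, got: ", bad[1])
  tx <- x$transcripts[match(codes$transcript_id, x$transcripts$transcript_id), ]
  if (anyNA(tx$transcript_id))
    stop("codes refer to transcripts absent from the annotation")

  orf <- vapply(tx$transcript_id, function(id)
    longest_orf(spliced_sequence(x, id, genome)), integer(1))
  ev <- evidence_flags(evidence, tx$transcript_id)
  rmax <- rpkm_max(expr, tx$transcript_id)

  prov <- data.frame(
    transcript_id = tx$transcript_id,
    gene_id = tx$gene_id,
    code = codes$code,
    class = lncrna_class(codes$code),
    length_nt = tx$exonic_length,
    n_exons = tx$n_exons,
    orf_nt = orf,
    rpkm_max = rmax,
    pass_a = tx$exonic_length >= criteria$min_length_nt &
      tx$n_exons >= criteria$min_exons,
    pass_b = !ev$cpc_coding & !ev$cnci_coding,
    pass_c = orf < criteria$max_orf_nt,
    pass_d = !ev$blastx_hit,
    pass_e = !ev$pfam_hit,
    pass_f = rmax >= criteria$min_rpkm_max,
    stringsAsFactors = FALSE)

  stages <- c(a_length_exons = "pass_a", b_cpc_cnci = "pass_b",
              c_orf = "pass_c", d_blastx = "pass_d", e_pfam = "pass_e",
              f_expression = "pass_f")
  alive <- rep(TRUE, nrow(prov))
  report <- data.frame(stage = names(stages),
                       n_input = NA_integer_, n_surviving = NA_integer_)
  for (k in seq_along(stages)) {
    report$n_input[k] <- sum(alive)
    alive <- alive & prov[[stages[k]]]
    report$n_surviving[k] <- sum(alive)
  }
  records <- prov[alive, , drop = FALSE]
  rownames(records) <- NULL
  lnc <- subset_annotation(x, records$transcript_id)
  if (nrow(lnc$exons)) {
    lnc$exons$biotype <-
      records$class[match(lnc$exons$transcript_id, records$transcript_id)]
    lnc <- annotation(lnc$exons, chrom_sizes = lnc$chrom_sizes)
  }
  list(records = records, provenance = prov, report = report, lncrna = lnc)
}

# max over samples of per-sample RPKM; absent features -> 0 with warning
rpkm_max <- function(expr, ids) {
  if (is.null(expr)) {
    warning("no expression table; rpkm_max set to 0 for all transcripts")
    return(stats::setNames(numeric(length(ids)), ids))
  }
  m <- rpkm_matrix(expr)
  out <- stats::setNames(numeric(length(ids)), ids)
  hit <- ids %in% rownames(m)
  if (any(!hit))
    warning(sum(!hit), " transcript(s) missing from expression table; ",
            "rpkm_max set to 0")
  if (any(hit))
    out[hit] <- apply(m[ids[hit], , drop = FALSE], 1, max)
  out
}

#' Class composition of an lncRNA set
#'
#' @param records survivor data.frame from [apply_filter_cascade()] (or
#'   any data.frame with a `class` and optionally `gene_id` column);
#'   alternatively a named integer vector of per-class counts.
#' @return data.frame `class`, `n_transcripts`, `n_loci` (NA when no
#'   gene ids are available), `pct` (half-up, 2 decimals); zero rows
#'   for an empty input.
#' @export
summarize_composition <- function(records) {
  if (is.numeric(records)) {
    cls <- names(records)
    n <- as.integer(records)
    loci <- rep(NA_integer_, length(n))
  } else {
    if (!nrow(records))
      return(data.frame(class = character(), n_transcripts = integer(),
                        n_loci = integer(), pct = numeric()))
    cls <- sort(unique(records$class))
    n <- vapply(cls, function(k) sum(records$class == k), integer(1))
    loci <- if ("gene_id" %in% names(records)) {
      vapply(cls, function(k)
        length(unique(records$gene_id[records$class == k])), integer(1))
    } else rep(NA_integer_, length(cls))
  }
  data.frame(class = cls, n_transcripts = n, n_loci = loci,
             pct = round_half_up(100 * n / sum(n), 2),
             row.names = NULL, stringsAsFactors = FALSE)
}
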