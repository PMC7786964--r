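#' Find neighbouring PCGs of anchor features
#'
#' Emits a pair for every (anchor locus, PCG) whose spans intersect or
#' lie within `max_dist` bp of each other (span gap, inclusive at the
#' threshold). Overlapping pairs get distance 0. Anchors and partners
#' are taken at the locus (gene) level; an anchor is never paired with
#' itself, so the same function computes the genome-wide PCG-PCG
#' control.
#'
#' @param anchors [annotation()] of anchor features (lncRNAs, or PCGs
#'   for the control set).
#' @param pcg PCG [annotation()].
#' @param max_dist maximum span gap in bp (inclusive).
#' @return data.frame `anchor_id`, `partner_id`, `distance`,
#'   `overlapping`, `orientation` (`"same"`/`"opposite"`).
#' @export
find_neighbors <- function(anchors, pcg, max_dist = 10000) {
  a <- gene_spans(anchors)
  g <- gene_spans(pcg)
  if (!nrow(a) || !nrow(g))
    return(data.frame(anchor_id = character(), partner_id = character(),
                      distance = integer(), overlapping = logical(),
                      orientation = character()))
  agr <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start, a$end))
  ggr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end))
  h <- quiet_overlaps(agr, ggr, maxgap = max_dist, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
  keep <- a$gene_id[qi] != g$gene_id[si]
  qi <- qi[keep]; si <- si[keep]
  gap <- pmax(a$start[qi], g$start[si]) - pmin(a$end[qi], g$end[si]) - 1L
  dist <- pmax(0L, gap)
  data.frame(anchor_id = a$gene_id[qi], partner_id = g$gene_id[si],
             distance = dist, overlapping = gap < 0L,
             orientation = ifelse(a$strand[qi] == g$strand[si],
                                  "same", "opposite"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pearson correlation of one expression-vector pair
#'
#' @param x,y expression vectors over the same groups (length >= 3).
#' @return list `pcc`, `p_value`; both NA when either vector has zero
#'   variance (such pairs are excluded from downstream distributions).
#' @export
pearson_pair <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need equal-length vectors of at least 3 groups")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(pcc = NA_real_, p_value = NA_real_))
  res <- pearson_cor(x, y)
  list(pcc = res$r, p_value = res$p_value)
}

#' Attach expression correlations to neighbour pairs
#'
#' @param pairs data.frame from [find_neighbors()].
#' @param profile features x groups matrix of replicate-averaged RPKM
#'   ([average_replicates()]); pairs with a member absent from the
#'   profile get NA.
#' @return `pairs` with `pcc` and `pcc_p` columns appended.
#' @export
correlate_pairs <- function(pairs, profile) {
  pcc <- pcc_p <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    aid <- pairs$anchor_id[i]; pid <- pairs$partner_id[i]
    if (aid %in% rownames(profile) && pid %in% rownames(profile)) {
      r <- pearson_pair(profile[aid, ], profile[pid, ])
      pcc[i] <- r$pcc; pcc_p[i] <- r$p_value
    }
  }
  pairs$pcc <- pcc
  pairs$pcc_p <- pcc_p
  pairs
}

#' Call cis-regulatory candidate pairs
#'
#' @param pairs data.frame with a `pcc` column ([correlate_pairs()]).
#' @param threshold pairs with `|pcc| > threshold` (strictly) are
#'   candidates.
#' @return list `candidates` (qualifying rows), `n_positive`,
#'   `n_negative` (sign tallies among candidates).
#' @export
call_cis_candidates <- function(pairs, threshold = 0.5) {
  hit <- !is.na(pairs$pcc) & abs(pairs$pcc) > threshold
  cand <- pairs[hit, , drop = FALSE]
  list(candidates = cand,
       n_positive = sum(cand$pcc > 0),
       n_negative = sum(cand$pcc < 0))
}

# stratum subsetting shared by compare_strata
pair_stratum <- function(pairs, stratum) {
  switch(stratum,
         "all" = pairs,
         "overlapping" = pairs[pairs$overlapping, , drop = FALSE],
         "non-overlapping" = pairs[!pairs$overlapping, , drop = FALSE],
         "overlapping-same" =
           pairs[pairs$overlapping & pairs$orientation == "same", ,
                 drop = FALSE],
         "overlapping-opposite" =
           pairs[pairs$overlapping & pairs$orientation == "opposite", ,
                 drop = FALSE],
         stop("unknown stratum: ", stratum))
}

#' Compare pair-correlation distributions between anchor classes
#'
#' Two-tailed Wilcoxon rank-sum test on the Pearson correlations of
#' lncRNA-coding vs coding-coding pairs, per stratum. Missing
#' correlations are dropped; a stratum empty on either side is skipped
#' (NA p).
#'
#' @param lnc_pairs,pcg_pairs correlated pair tables
#'   ([correlate_pairs()]).
#' @param strata strata to evaluate.
#' @return data.frame `stratum`, `n_lnc`, `n_pcg`, `statistic`, `p`.
#' @export
compare_strata <- function(lnc_pairs, pcg_pairs,
                           strata = c("all", "overlapping",
                                      "non-overlapping",
                                      "overlapping-same",
                                      "overlapping-opposite")) {
  out <- lapply(strata, function(s) {
    x <- pair_stratum(lnc_pairs, s)$pcc
    y <- pair_stratum(pcg_pairs, s)$pcc
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) || !length(y))
      return(data.frame(stratum = s, n_lnc = length(x), n_pcg = length(y),
                        statistic = NA_real_, p = NA_real_))
    t <- wilcoxon_rank_sum(x, y)
    data.frame(stratum = s, n_lnc = length(x), n_pcg = length(y),
               statistic = t$statistic, p = t$p_value)
  })
  do.call(rbind, out)
}

#' Hypergeometric GO-term enrichment with BH correction
#'
#' For each term annotated to `K` background genes and `k` query genes
#' (query of size `n`, background of size `N`), the enrichment p-value
#' is `P(X >= k)` under the hypergeometric distribution;
#' Benjamini-Hochberg q-values are computed across all tested terms and
#' terms with `q < 0.05` are flagged significant. Terms absent from the
#' background are skipped.
#'
#' @param query character vector of genes, a subset of `background`.
#' @param background character vector of all genes in the universe.
#' @param go GO annotations ([read_go_annotations()] output or a named
#'   list gene -> terms).
#' @return data.frame `term`, `k`, `n`, `K`, `N`, `p`, `q`,
#'   `significant`, sorted by p.
#' @export
go_enrichment <- function(query, background, go) {
  gene2terms <- if (is.list(go) && !is.null(go$gene2terms)) go$gene2terms
                else go
  if (length(setdiff(query, background)))
    stop("query genes must be a subset of the background")
  background <- unique(background)
  query <- unique(query)
  bg_terms <- gene2terms[intersect(background, names(gene2terms))]
  term_bg <- table(unlist(bg_terms))
  if (!length(term_bg))
    return(data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      q = numeric(), significant = logical()))
  q_terms <- gene2terms[intersect(query, names(gene2terms))]
  term_q <- table(unlist(q_terms))
  N <- length(background)
  n <- length(query)
  terms <- names(term_bg)
  K <- as.integer(term_bg)
  k <- as.integer(term_q[terms])
  k[is.na(k)] <- 0L
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = terms, k = k, n = n, K = K, N = N, p = p,
                    q = bh_adjust(p), stringsAsFactors = FALSE)
  out$significant <- out$q < 0.05
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  out
}
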