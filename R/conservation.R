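#' Summarize BLAST tabular hits at an E-value cutoff
#'
#' @param hits data.frame from [read_blast_tabular()], one query set
#'   against one target (a genome or a set of lncRNA transcripts).
#' @param cutoff keep rows with `evalue <= cutoff`.
#' @param query_ids optional universe of query ids; hits from queries
#'   outside it are counted with a warning.
#' @param count_targets also count distinct subjects hit (used when the
#'   targets are lncRNA transcripts).
#' @return list `cutoff`, `n_query_hit` (distinct queries with >= 1
#'   hit, each counted once regardless of hit multiplicity) and
#'   `n_target_hit` (distinct subjects, or NA).
#' @export
summarize_blast <- function(hits, cutoff, query_ids = NULL,
                            count_targets = FALSE) {
  keep <- hits[!is.na(hits$evalue) & hits$evalue <= cutoff, , drop = FALSE]
  if (!is.null(query_ids)) {
    unknown <- setdiff(unique(keep$qseqid), query_ids)
    if (length(unknown))
      warning(length(unknown), " hit query id(s) not in the query set")
  }
  list(cutoff = cutoff,
       n_query_hit = length(unique(keep$qseqid)),
       n_target_hit = if (count_targets) length(unique(keep$sseqid))
                      else NA_integer_)
}

#' Relative decrease between two hit counts
#'
#' Percentage drop from the looser to the stricter E-value cutoff,
#' half-up at 2 decimals.
#'
#' @param n_loose count at the loose cutoff (e.g. 1e-3).
#' @param n_strict count at the strict cutoff (e.g. 1e-10),
#'   `<= n_loose`.
#' @return `100 * (n_loose - n_strict) / n_loose`; NA when `n_loose`
#'   is 0.
#' @export
relative_decrease <- function(n_loose, n_strict) {
  stopifnot(n_strict >= 0, n_loose >= n_strict)
  if (n_loose == 0) return(NA_real_)
  round_half_up(100 * (n_loose - n_strict) / n_loose, 2)
}

# gene-level spans of an annotation (min/max over the gene's exons)
gene_spans <- function(x) {
  ex <- x$exons
  sp <- split(seq_len(nrow(ex)), ex$gene_id)
  data.frame(
    gene_id = names(sp),
    chrom = vapply(sp, function(i) ex$chrom[i[1]], character(1)),
    strand = vapply(sp, function(i) ex$strand[i[1]], character(1)),
    start = vapply(sp, function(i) min(ex$start[i]), integer(1)),
    end = vapply(sp, function(i) max(ex$end[i]), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Flanking PCG neighbourhood of an lncRNA locus
#'
#' The `k` nearest protein-coding genes strictly left and right of the
#' locus span by genomic coordinate, nearest first, strand-agnostic. A
#' PCG overlapping the locus is assigned to the side of its midpoint.
#'
#' @param locus list or one-row data.frame with `gene_id` (locus id),
#'   `chrom`, `start`, `end`.
#' @param pcg PCG [annotation()] (or a precomputed [gene_spans()]
#'   table).
#' @param k genes kept per side.
#' @return list `lnc_locus_id`, `chrom`, `left`, `right` (character
#'   vectors of gene ids, nearest first; shorter than `k` at
#'   chromosome ends, empty when the chromosome holds no PCGs).
#' @export
build_neighborhood <- function(locus, pcg, k = 3) {
  genes <- if (inherits(pcg, "lnc_annotation")) gene_spans(pcg) else pcg
  g <- genes[genes$chrom == locus$chrom, , drop = FALSE]
  mid_locus <- (locus$start + locus$end) / 2
  if (nrow(g)) {
    mid <- (g$start + g$end) / 2
    side <- ifelse(g$end < locus$start, "left",
            ifelse(g$start > locus$end, "right",
                   ifelse(mid < mid_locus, "left", "right")))
    gl <- g[side == "left", , drop = FALSE]
    gl <- gl[order(-gl$end), , drop = FALSE]
    gr <- g[side == "right", , drop = FALSE]
    gr <- gr[order(gr$start), , drop = FALSE]
    left <- utils::head(gl$gene_id, k)
    right <- utils::head(gr$gene_id, k)
  } else {
    left <- right <- character()
  }
  list(lnc_locus_id = locus$gene_id, chrom = locus$chrom,
       left = left, right = right)
}

# gene -> ortholog-group lookups for the two species
ortholog_maps <- function(orthologs) {
  list(a = stats::setNames(orthologs$group_id, orthologs$gene_a),
       b = stats::setNames(orthologs$group_id, orthologs$gene_b))
}

#' Test a cross-species lncRNA pair for synteny
#'
#' Neighbourhood PCGs are mapped to their ortholog groups; `shared` is
#' the set of groups present in both neighbourhoods (a group is counted
#' once, so tandem paralogs do not inflate the tally). The pair is
#' accepted iff at least `min_shared` groups are shared and, in each
#' species' neighbourhood, the shared groups include at least one gene
#' from its left list and one from its right list. Sides are evaluated
#' per species, so a locally inverted block (a group left of the locus
#' in one species, right in the other) still qualifies;
#' `side_consistent = TRUE` additionally demands a shared group on the
#' left in both species and one on the right in both.
#'
#' @param nA,nB neighbourhoods from [build_neighborhood()] for species
#'   A and B respectively.
#' @param orthologs data.frame from [read_ortholog_table()] (`gene_a`
#'   from species A, `gene_b` from species B).
#' @param min_shared minimum number of shared ortholog groups.
#' @param side_consistent require cross-species side agreement.
#' @return list `accepted`, `shared_groups`, `left_support` and
#'   `right_support` (shared-group counts per species side).
#' @export
syntenic_pair <- function(nA, nB, orthologs, min_shared = 3,
                          side_consistent = FALSE) {
  maps <- ortholog_maps(orthologs)
  grp <- function(genes, map) unique(unname(map[genes[genes %in% names(map)]]))
  gA <- grp(c(nA$left, nA$right), maps$a)
  gB <- grp(c(nB$left, nB$right), maps$b)
  shared <- intersect(gA, gB)
  lA <- intersect(grp(nA$left, maps$a), shared)
  rA <- intersect(grp(nA$right, maps$a), shared)
  lB <- intersect(grp(nB$left, maps$b), shared)
  rB <- intersect(grp(nB$right, maps$b), shared)
  ok <- length(shared) >= min_shared &&
    length(lA) > 0 && length(rA) > 0 && length(lB) > 0 && length(rB) > 0
  if (ok && side_consistent)
    ok <- length(intersect(lA, lB)) > 0 && length(intersect(rA, rB)) > 0
  list(accepted = ok, shared_groups = shared,
       left_support = c(a = length(lA), b = length(lB)),
       right_support = c(a = length(rA), b = length(rB)))
}

#' Group accepted syntenic pairs into cross-species families
#'
#' Families are the connected components of the bipartite graph whose
#' edges are the accepted pairs; loci without any accepted pair belong
#' to no family.
#'
#' @param pairs data.frame with columns `locus_a`, `locus_b` (accepted
#'   pairs; species-A and species-B locus ids).
#' @return list `families` (data.frame `family_id`, `species`,
#'   `locus_id`) and `summary` (`n_families`, per-species locus
#'   counts).
#' @export
build_families <- function(pairs) {
  if (!nrow(pairs))
    return(list(families = data.frame(family_id = integer(),
                                      species = character(),
                                      locus_id = character()),
                summary = c(n_families = 0L, n_loci_a = 0L, n_loci_b = 0L)))
  edges <- data.frame(from = paste0("A|", pairs$locus_a),
                      to = paste0("B|", pairs$locus_b))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(g)
  node <- names(comp$membership)
  fam <- data.frame(
    family_id = unname(comp$membership),
    species = ifelse(startsWith(node, "A|"), "A", "B"),
    locus_id = sub("^[AB]\\|", "", node),
    stringsAsFactors = FALSE)
  fam <- fam[order(fam$family_id, fam$species, fam$locus_id), ]
  rownames(fam) <- NULL
  list(families = fam,
       summary = c(n_families = comp$no,
                   n_loci_a = sum(fam$species == "A"),
                   n_loci_b = sum(fam$species == "B")))
}

#' Build syntenic families between two species' lncRNA sets
#'
#' Convenience driver: builds the neighbourhood of every lncRNA locus
#' in both species, tests all cross-species locus pairs and groups the
#' accepted ones into families. Intended for locus sets of desk scale
#' (all pairs are examined).
#'
#' @param lnc_a,lnc_b lncRNA [annotation()]s (loci = gene ids).
#' @param pcg_a,pcg_b PCG reference [annotation()]s.
#' @param orthologs [read_ortholog_table()] output.
#' @param k flanking genes per side.
#' @param min_shared,side_consistent see [syntenic_pair()].
#' @return list `pairs` (accepted pairs), plus the elements of
#'   [build_families()].
#' @export
synteny_families <- function(lnc_a, lnc_b, pcg_a, pcg_b, orthologs,
                             k = 3, min_shared = 3,
                             side_consistent = FALSE) {
  ga <- gene_spans(pcg_a); gb <- gene_spans(pcg_b)
  la <- gene_spans(lnc_a); lb <- gene_spans(lnc_b)
  nb_a <- lapply(seq_len(nrow(la)), function(i)
    build_neighborhood(la[i, ], ga, k))
  nb_b <- lapply(seq_len(nrow(lb)), function(i)
    build_neighborhood(lb[i, ], gb, k))
  acc <- list()
  for (i in seq_along(nb_a)) {
    for (j in seq_along(nb_b)) {
      sp <- syntenic_pair(nb_a[[i]], nb_b[[j]], orthologs,
                          min_shared = min_shared,
                          side_consistent = side_consistent)
      if (sp$accepted)
        acc[[length(acc) + 1L]] <- data.frame(
          locus_a = la$gene_id[i], locus_b = lb$gene_id[j],
          n_shared = length(sp$shared_groups), stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(acc)) do.call(rbind, acc)
           else data.frame(locus_a = character(), locus_b = character(),
                           n_shared = integer())
  c(list(pairs = pairs), build_families(pairs))
}
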