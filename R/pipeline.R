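#' Run the full lncRNA landscape pipeline
#'
#' Orchestrates the stages in dependency order: context classification
#' of the assembled transcripts, the lncRNA filter cascade, expression
#' specificity scoring, genomic feature statistics and TE overlap,
#' sex-bias calling on the DE table, synteny families against the
#' second species, neighbour-pair correlation and GO enrichment of the
#' cis partners. Every stage's table is written under `out_dir` and the
#' summary returned.
#'
#' @param config named list (or path to a YAML file, requires the yaml
#'   package) with an `inputs` element of file paths: `genome_a`,
#'   `ref_a`, `candidates_a`, `te`, `counts`, `groups`, `lengths`,
#'   `library_sizes`, `de`, and optionally `evidence`, `ref_b`,
#'   `lnc_b`, `orthologs`, `go`. Optional `params`: `js_threshold`,
#'   `cis_threshold`, `max_dist`, `min_shared`.
#' @param out_dir output directory.
#' @return list of per-stage results (invisible file side effects).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  inp <- config$inputs
  required <- c("genome_a", "ref_a", "candidates_a", "te", "counts",
                "groups", "lengths", "library_sizes", "de")
  miss <- setdiff(required, names(inp))
  if (length(miss)) stop("config lacks inputs: ", paste(miss, collapse = ", "))
  absent <- unlist(inp)[!file.exists(unlist(inp))]
  if (length(absent))
    stop("input file(s) not found: ", paste(absent, collapse = ", "))
  prm <- config$params %||% list()
  js_thr <- prm$js_threshold %||% 0.95
  cis_thr <- prm$cis_threshold %||% 0.5
  max_dist <- prm$max_dist %||% 10000
  min_shared <- prm$min_shared %||% 3
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  res <- list()

  genome <- read_genome_fasta(inp$genome_a)
  ref <- read_gtf(inp$ref_a, chrom_sizes = genome_sizes(genome))
  cand <- read_gtf(inp$candidates_a, chrom_sizes = genome_sizes(genome))

  # stage: classify
  codes <- classify_transcripts(cand, ref)
  write_tsv(codes, p("codes.tsv"))
  res$codes <- codes

  # stage: identify
  grp <- read_tsv_checked(inp$groups, c("sample", "group"),
                          c("character", "character"), header = TRUE)
  len <- read_tsv_checked(inp$lengths, c("feature_id", "length"),
                          c("character", "numeric"), header = TRUE)
  lib <- read_tsv_checked(inp$library_sizes, c("sample", "mapped_reads"),
                          c("character", "numeric"), header = TRUE)
  expr <- expression_table(read_counts_table(inp$counts),
                           stats::setNames(len$length, len$feature_id),
                           stats::setNames(grp$group, grp$sample),
                           stats::setNames(lib$mapped_reads, lib$sample))
  evidence <- if (!is.null(inp$evidence)) read_evidence_table(inp$evidence)
              else NULL
  keep <- codes[codes$code %in% c("u", "i", "x"), , drop = FALSE]
  ident <- apply_filter_cascade(subset_annotation(cand, keep$transcript_id),
                                keep, genome, evidence, expr)
  write_gtf(ident$lncrna, p("lncRNA.gtf"))
  write_tsv(ident$report, p("filter_report.tsv"))
  write_tsv(ident$records, p("lncRNA_records.tsv"))
  res$identify <- ident
  res$composition <- summarize_composition(ident$records)
  write_tsv(res$composition, p("composition.tsv"))

  # stage: specificity (tissue groups only, per the study design)
  profile <- average_replicates(expr)
  tissue_groups <- intersect(c("Ag", "Ma", "Fa", "Tes", "Ov", "Mhd",
                               "Fhd", "Mmg", "Fmg"),
                             unique(expr$sample_groups))
  if (length(tissue_groups) < 2L) tissue_groups <- unique(expr$sample_groups)
  tprof <- profile[, tissue_groups, drop = FALSE]
  pcg_ids <- intersect(unique(ref$transcripts$gene_id), rownames(tprof))
  lnc_ids <- intersect(ident$records$transcript_id, rownames(tprof))
  sc_pcg <- specificity_scores(tprof[pcg_ids, , drop = FALSE])
  sc_lnc <- specificity_scores(tprof[lnc_ids, , drop = FALSE])
  write_tsv(sc_pcg, p("specificity_pcg.tsv"))
  write_tsv(sc_lnc, p("specificity_lnc.tsv"))
  res$specificity <- list(
    pcg = sc_pcg, lnc = sc_lnc,
    ks = compare_specificity(sc_lnc$js_score, sc_pcg$js_score),
    highly_specific_pcg = call_highly_specific(sc_pcg, js_thr))

  # stage: features
  te <- read_te_track(inp$te)
  res$te <- te_overlap(ident$lncrna, ref, te)
  res$te_composition <- list(lnc = te_class_composition(res$te$hits_a),
                             pcg = te_class_composition(res$te$hits_b))
  res$sizes <- list(lnc = size_stats(ident$lncrna), pcg = size_stats(ref))
  res$chrom_dist <- chromosome_distribution(ident$lncrna, ref)
  write_tsv(res$chrom_dist$counts, p("chromosome_distribution.tsv"))

  # stage: sex bias
  de <- read_de_table(inp$de)
  lnc_loci <- unique(ident$records$gene_id)
  bias <- call_biased(de)
  is_lnc_feat <- de$feature_id %in% c(ident$records$transcript_id, lnc_loci)
  lnc_feats <- de$feature_id[is_lnc_feat]
  counts2 <- c(pcg_male = sum(!(bias$up %in% lnc_feats)),
               pcg_female = sum(!(bias$down %in% lnc_feats)),
               lnc_male = sum(bias$up %in% lnc_feats),
               lnc_female = sum(bias$down %in% lnc_feats))
  res$sexbias <- list(counts = counts2,
                      test = sex_bias_fisher(counts2["pcg_male"],
                                             counts2["pcg_female"],
                                             counts2["lnc_male"],
                                             counts2["lnc_female"]))

  # stage: synteny (optional second species)
  if (!is.null(inp$ref_b) && !is.null(inp$lnc_b) &&
      !is.null(inp$orthologs)) {
    ref_b <- read_gtf(inp$ref_b)
    lnc_b <- read_gtf(inp$lnc_b)
    orth <- read_ortholog_table(inp$orthologs)
    res$synteny <- synteny_families(ident$lncrna, lnc_b, ref, ref_b,
                                    orth, min_shared = min_shared)
    write_tsv(res$synteny$families, p("synteny_families.tsv"))
  }

  # stage: neighbours + GO enrichment
  pairs <- find_neighbors(ident$lncrna, ref, max_dist = max_dist)
  loc_prof <- profile
  tx2loc <- stats::setNames(ident$records$gene_id,
                            ident$records$transcript_id)
  hit <- rownames(loc_prof) %in% names(tx2loc)
  rownames(loc_prof)[hit] <- tx2loc[rownames(loc_prof)[hit]]
  pairs <- correlate_pairs(pairs, loc_prof)
  write_tsv(pairs, p("neighbor_pairs.tsv"))
  res$pairs <- pairs
  res$cis <- call_cis_candidates(pairs, threshold = cis_thr)
  ctrl <- correlate_pairs(find_neighbors(ref, ref, max_dist = max_dist),
                          loc_prof)
  res$control_pairs <- ctrl
  res$strata <- compare_strata(pairs, ctrl)
  if (!is.null(inp$go)) {
    go <- read_go_annotations(inp$go)
    bg <- unique(ref$transcripts$gene_id)
    query <- intersect(unique(res$cis$candidates$partner_id), bg)
    if (length(query)) {
      res$go <- go_enrichment(query, bg, go)
      write_tsv(res$go, p("go_enrichment.tsv"))
    }
  }

  # summary report
  report <- data.frame(
    metric = c("n_candidates", "n_lncRNA",
               paste0("pct_", res$composition$class),
               "te_overlap_lnc_pct", "n_cis_candidates",
               "n_synteny_families"),
    value = c(n_transcripts(cand), nrow(ident$records),
              res$composition$pct,
              round_half_up(100 * mean(res$te$flags_a), 2),
              nrow(res$cis$candidates),
              if (!is.null(res$synteny))
                unname(res$synteny$summary["n_families"]) else NA))
  write_tsv(report, p("report.tsv"))
  res$report <- report
  res
}
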