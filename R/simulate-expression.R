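# expression-layer generators for the synthetic study

# one mean-RPKM profile over the given groups
profile_of_type <- function(type, groups, dominant = NA) {
  n <- length(groups)
  v <- switch(type,
    housekeeping = stats::rlnorm(1, log(30), 0.4) *
      exp(stats::rnorm(n, 0, 0.15)),
    moderate = stats::rlnorm(1, log(10), 0.3) *
      exp(stats::rnorm(n, 0, 0.2)),
    specific = {
      x <- exp(stats::rnorm(n, log(0.3), 0.3))
      x[match(dominant, groups)] <- stats::rlnorm(1, log(80), 0.3)
      x
    },
    testis = {
      x <- exp(stats::rnorm(n, log(2), 0.3))
      x[match("Tes", groups)] <- stats::rlnorm(1, log(60), 0.3)
      x[match("Ov", groups)] <- 0.3
      x
    },
    ovary = {
      x <- exp(stats::rnorm(n, log(2), 0.3))
      x[match("Ov", groups)] <- stats::rlnorm(1, log(60), 0.3)
      x[match("Tes", groups)] <- 0.3
      x
    },
    low = stats::runif(n, 0.0005, 0.005),
    stop("unknown profile type: ", type))
  stats::setNames(v, groups)
}

#' Simulate planted tissue-specificity profiles
#'
#' Mean-RPKM profiles for a planted tissue-specific fraction (one
#' dominant group each) and a housekeeping fraction (near-uniform).
#' With `noise = FALSE` the specific profiles are exactly one-hot and
#' the housekeeping profiles exactly uniform.
#'
#' @param n_specific,n_housekeeping genes per class.
#' @param groups group names (default: the 9 tissue groups).
#' @param seed integer seed.
#' @param noise add biological variability.
#' @return list `profile` (matrix genes x groups) and `truth`
#'   (data.frame `feature_id`, `type`, `dominant`).
#' @export
simulate_profiles <- function(n_specific = 500, n_housekeeping = 500,
                              groups = c("Ag", "Ma", "Fa", "Tes", "Ov",
                                         "Mhd", "Fhd", "Mmg", "Fmg"),
                              seed = 1, noise = TRUE) {
  set.seed(seed)
  n <- n_specific + n_housekeeping
  type <- rep(c("specific", "housekeeping"),
              c(n_specific, n_housekeeping))
  dominant <- rep(NA_character_, n)
  dominant[seq_len(n_specific)] <-
    groups[(seq_len(n_specific) - 1L) %% length(groups) + 1L]
  prof <- matrix(0, n, length(groups),
                 dimnames = list(sprintf("gene%04d", seq_len(n)), groups))
  for (i in seq_len(n)) {
    if (noise) {
      prof[i, ] <- profile_of_type(type[i], groups, dominant[i])
    } else {
      prof[i, ] <- if (type[i] == "specific") {
        x <- numeric(length(groups)); x[match(dominant[i], groups)] <- 50; x
      } else rep(10, length(groups))
    }
  }
  list(profile = prof,
       truth = data.frame(feature_id = rownames(prof), type = type,
                          dominant = dominant, stringsAsFactors = FALSE))
}

#' Simulate expression-profile pairs with a planted correlation
#'
#' Each pair shares a latent profile `z ~ N(60, 40)` (truncated below
#' at 0.5) over the groups; both members observe `z` plus independent
#' Gaussian noise whose variance is chosen so the population Pearson
#' correlation between the two members equals `rho`. `rho = 0` gives
#' independent latent profiles.
#'
#' @param n_pairs number of pairs.
#' @param rho target correlation in `[0, 1]`.
#' @param groups group names (default: all 14 study groups).
#' @param seed integer seed.
#' @return list `x`, `y` (matrices `n_pairs` x groups).
#' @export
simulate_pair_profiles <- function(n_pairs, rho,
                                   groups = c("Ag", "Ma", "Fa", "Tes",
                                              "Ov", "Mhd", "Fhd", "Mmg",
                                              "Fmg", "E1", "E4", "L5",
                                              "FP", "AF"),
                                   seed = 1) {
  stopifnot(rho >= 0, rho <= 1)
  set.seed(seed)
  n <- length(groups)
  sd_z <- 40
  x <- y <- matrix(0, n_pairs, n,
                   dimnames = list(sprintf("pair%04d", seq_len(n_pairs)),
                                   groups))
  for (i in seq_len(n_pairs)) {
    if (rho > 0) {
      z <- stats::rnorm(n, 60, sd_z)
      s <- sd_z * sqrt((1 - rho) / rho)
      x[i, ] <- z + stats::rnorm(n, 0, s)
      y[i, ] <- z + stats::rnorm(n, 0, s)
    } else {
      x[i, ] <- stats::rnorm(n, 60, sd_z)
      y[i, ] <- stats::rnorm(n, 60, sd_z)
    }
  }
  x <- pmax(x, 0.5)
  y <- pmax(y, 0.5)
  list(x = x, y = y)
}

#' Generate per-sample counts, group map and DE table
#'
#' Every PCG locus and candidate transcript gets a planted mean-RPKM
#' profile over the 14 groups (housekeeping, tissue-specific,
#' testis-/ovary-dominant, low-abundance for the expression decoys);
#' paired intergenic lncRNAs and their nearest PCG share a latent
#' profile at the configured correlation. Counts per sample are
#' negative-binomial around `RPKM * L * N / 1e9` at the configured
#' dispersion (deterministic rounding at dispersion 0). The
#' testis-vs-ovary DE table is derived from the planted profiles.
#'
#' @param cfg a [sim_config()].
#' @param ann output of [generate_annotations()].
#' @return list `expr` ([expression_table()]), `profile_truth`,
#'   `pair_truth`, `de` (DE table data.frame), `groups`, and
#'   `feature_map` (transcript -> locus).
#' @export
generate_expression <- function(cfg, ann) {
  set.seed(cfg$seed + 2L)
  groups <- c(cfg$tissues, cfg$stages)
  tx_truth <- ann$truth$transcripts
  pcg_genes <- sort(unique(ann$ref_a$transcripts$gene_id))
  cand <- ann$candidates_a$transcripts

  # --- assign profile types (tissue-specific PCGs are drawn from genes
  # that are not cis-pair partners, whose profiles are set by the pair
  # machinery below)
  u_tr <- tx_truth[tx_truth$type == "lnc_u", ]
  partner_of_u <- sprintf("PCG_%s_%02d", sub("chrA", "", u_tr$chrom),
                          u_tr$slot)
  n_pcg <- length(pcg_genes)
  pcg_type <- stats::setNames(rep("housekeeping", n_pcg), pcg_genes)
  pcg_dom <- stats::setNames(rep(NA_character_, n_pcg), pcg_genes)
  non_partner <- setdiff(pcg_genes, partner_of_u)
  n_spec <- min(round(cfg$tissue_specific_frac * n_pcg),
                length(non_partner))
  pcg_type[non_partner[seq_len(n_spec)]] <- "specific"
  pcg_dom[non_partner[seq_len(n_spec)]] <-
    cfg$tissues[(seq_len(n_spec) - 1L) %% length(cfg$tissues) + 1L]

  lnc_ids <- tx_truth$transcript_id[tx_truth$is_lnc]
  u_ids <- tx_truth$transcript_id[tx_truth$type == "lnc_u"]
  n_u <- length(u_ids)
  paired <- u_ids[seq_len(round(cfg$cis_frac * n_u))]
  unpaired_lnc <- setdiff(lnc_ids, paired)
  n_tes <- round(cfg$testis_biased_lnc_frac * length(lnc_ids))
  n_ov <- round(cfg$ovary_biased_lnc_frac * length(lnc_ids))
  lnc_type <- stats::setNames(rep("moderate", length(unpaired_lnc)),
                              unpaired_lnc)
  lnc_type[seq_len(min(n_tes, length(unpaired_lnc)))] <- "testis"
  if (n_ov > 0 && length(unpaired_lnc) > n_tes)
    lnc_type[n_tes + seq_len(min(n_ov, length(unpaired_lnc) - n_tes))] <-
      "ovary"
  nonrepro <- setdiff(cfg$tissues, c("Tes", "Ov"))
  rest <- names(lnc_type)[lnc_type == "moderate"]
  n_lspec <- round(cfg$lnc_specific_frac * length(rest))
  lnc_dom <- stats::setNames(rep(NA_character_, length(unpaired_lnc)),
                             unpaired_lnc)
  if (n_lspec > 0) {
    lnc_type[rest[seq_len(n_lspec)]] <- "specific"
    lnc_dom[rest[seq_len(n_lspec)]] <-
      nonrepro[(seq_len(n_lspec) - 1L) %% length(nonrepro) + 1L]
  }

  # --- build the mean profile matrix
  other_ids <- tx_truth$transcript_id[!tx_truth$is_lnc]
  other_type <- ifelse(tx_truth$type[!tx_truth$is_lnc] == "lowexpr",
                       "low", "moderate")
  feats <- c(pcg_genes, lnc_ids, other_ids)
  prof <- matrix(0, length(feats), length(groups),
                 dimnames = list(feats, groups))
  ptype <- stats::setNames(rep(NA_character_, length(feats)), feats)
  pdom <- stats::setNames(rep(NA_character_, length(feats)), feats)
  for (g in pcg_genes) {
    prof[g, ] <- profile_of_type(pcg_type[g], groups, pcg_dom[g])
    ptype[g] <- pcg_type[g]
    pdom[g] <- pcg_dom[g]
  }
  for (id in unpaired_lnc) {
    prof[id, ] <- profile_of_type(lnc_type[id], groups, lnc_dom[id])
    ptype[id] <- lnc_type[id]
    pdom[id] <- lnc_dom[id]
  }
  for (j in seq_along(other_ids)) {
    prof[other_ids[j], ] <- profile_of_type(other_type[j], groups)
    ptype[other_ids[j]] <- other_type[j]
  }

  # --- planted cis pairs: u-lncRNA with its own slot's PCG
  pair_rows <- list()
  pp <- simulate_pair_profiles(length(u_ids), cfg$cis_rho, groups,
                               seed = cfg$seed + 3L)
  for (j in seq_along(u_ids)) {
    id <- u_ids[j]
    tr <- tx_truth[tx_truth$transcript_id == id, ]
    partner <- sprintf("PCG_%s_%02d",
                       sub("chrA", "", tr$chrom), tr$slot)
    is_paired <- id %in% paired
    if (is_paired) {
      prof[id, ] <- pp$x[j, ]
      prof[partner, ] <- pp$y[j, ]
      ptype[id] <- ptype[partner] <- "paired"
    }
    pair_rows[[j]] <- data.frame(
      anchor_locus = tr$gene_id, anchor_tx = id, partner_gene = partner,
      rho = if (is_paired) cfg$cis_rho else 0, stringsAsFactors = FALSE)
  }
  pair_truth <- do.call(rbind, pair_rows)

  # --- counts
  reps <- cfg$replicates[groups]
  samples <- unlist(lapply(groups, function(g)
    paste0(g, "_r", seq_len(reps[g]))))
  sample_groups <- stats::setNames(rep(groups, reps[groups]), samples)
  feat_len <- c(
    stats::setNames(vapply(pcg_genes, function(g)
      sum(with(ann$ref_a$exons[ann$ref_a$exons$gene_id == g, ],
               end - start + 1L)), integer(1)), pcg_genes),
    stats::setNames(cand$exonic_length, cand$transcript_id)[c(lnc_ids, other_ids)])
  N <- stats::setNames(rep(cfg$library_size, length(samples)), samples)
  counts <- matrix(0, length(feats), length(samples),
                   dimnames = list(feats, samples))
  for (s in samples) {
    mu <- prof[, sample_groups[s]] * feat_len[feats] * N[s] / 1e9
    counts[, s] <- if (cfg$nb_dispersion > 0)
      stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
    else round(mu)
  }
  expr <- expression_table(counts, feat_len, sample_groups, N)

  # --- testis-vs-ovary DE table from the planted profiles
  de_feats <- c(pcg_genes, lnc_ids)
  lfc <- log2((prof[de_feats, "Tes"] + 0.1) / (prof[de_feats, "Ov"] + 0.1))
  biased <- abs(lfc) >= 1
  padj <- ifelse(biased, 10^-stats::runif(length(lfc), 4, 12),
                 stats::runif(length(lfc), 0.1, 0.95))
  de <- data.frame(feature_id = de_feats, log2fc = as.numeric(lfc),
                   pvalue = padj / 2, padj = padj,
                   stringsAsFactors = FALSE, row.names = NULL)

  profile_truth <- data.frame(feature_id = feats, type = unname(ptype),
                              dominant = unname(pdom),
                              stringsAsFactors = FALSE)
  list(expr = expr, profile = prof, profile_truth = profile_truth,
       pair_truth = pair_truth, de = de, groups = groups,
       feature_map = stats::setNames(cand$gene_id, cand$transcript_id))
}

#' Generate GO annotations with one planted enriched term
#'
#' Background terms are assigned uniformly at random to every PCG; the
#' planted term `GO:T001` is concentrated in the designated gene set
#' (by default the PCG partners of the planted cis pairs) plus a few
#' background genes.
#'
#' @param cfg a [sim_config()].
#' @param ann output of [generate_annotations()].
#' @param designated gene set carrying the planted term; defaults to
#'   the partners of the correlated planted pairs when `expr_out` is
#'   given.
#' @param expr_out optional [generate_expression()] output used for
#'   the default designated set.
#' @return list `gene2terms`, `planted_term`, `designated`.
#' @export
generate_go <- function(cfg, ann, designated = NULL, expr_out = NULL) {
  set.seed(cfg$seed + 4L)
  genes <- sort(unique(ann$ref_a$transcripts$gene_id))
  pool <- sprintf("GO:B%03d", 1:40)
  gene2terms <- lapply(stats::setNames(genes, genes), function(g)
    sample(pool, 3L))
  if (is.null(designated)) {
    designated <- if (!is.null(expr_out))
      unique(expr_out$pair_truth$partner_gene[expr_out$pair_truth$rho > 0])
    else character()
  }
  planted <- "GO:T001"
  extra <- utils::head(setdiff(genes, designated), 3L)
  for (g in c(designated, extra))
    gene2terms[[g]] <- c(gene2terms[[g]], planted)
  list(gene2terms = gene2terms, planted_term = planted,
       designated = designated)
}

#' Run the full synthetic-study generator
#'
#' @param cfg a [sim_config()].
#' @return list bundling every layer: `config`, `genomes`
#'   (`DNAStringSet` per species), `ref_a`, `candidates_a`, `ref_b`,
#'   `lnc_b`, `te`, `evidence`, `orthologs`, `expr`, `profile`, `de`,
#'   `go` and `truth` (`transcripts`, `synteny`, `profiles`, `pairs`).
#' @export
simulate_study <- function(cfg = sim_config()) {
  genomes <- generate_genomes(cfg)
  ann <- generate_annotations(cfg, genomes)
  ex <- generate_expression(cfg, ann)
  go <- generate_go(cfg, ann, expr_out = ex)
  list(config = cfg,
       genomes = list(a = Biostrings::DNAStringSet(ann$genomes$a),
                      b = Biostrings::DNAStringSet(ann$genomes$b)),
       ref_a = ann$ref_a, candidates_a = ann$candidates_a,
       ref_b = ann$ref_b, lnc_b = ann$lnc_b,
       te = ann$te, evidence = ann$evidence, orthologs = ann$orthologs,
       expr = ex$expr, profile = ex$profile, de = ex$de, go = go,
       groups = ex$groups, feature_map = ex$feature_map,
       truth = list(transcripts = ann$truth$transcripts,
                    synteny = ann$truth$synteny,
                    profiles = ex$profile_truth,
                    pairs = ex$pair_truth))
}

#' Write a simulated study to disk
#'
#' Serializes every layer in the pipeline's external formats: FASTA
#' genomes, GTF annotations, a BED TE track (converted back to 0-based
#' half-open), count/group/length/library tables, evidence, DE,
#' ortholog and GO tables, plus the truth tables as TSV.
#'
#' @param sim output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_study_files <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(sim$genomes$a, p("genome_a.fa"))
  Biostrings::writeXStringSet(sim$genomes$b, p("genome_b.fa"))
  write_gtf(sim$ref_a, p("ref_a.gtf"))
  write_gtf(sim$candidates_a, p("candidates_a.gtf"))
  write_gtf(sim$ref_b, p("ref_b.gtf"))
  write_gtf(sim$lnc_b, p("lnc_b.gtf"))
  te <- sim$te
  te$start <- te$start - 1L  # back to BED half-open
  utils::write.table(te, p("te.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  cnt <- data.frame(feature_id = rownames(sim$expr$counts),
                    sim$expr$counts, check.names = FALSE)
  write_tsv(cnt, p("counts.tsv"))
  write_tsv(data.frame(sample = names(sim$expr$sample_groups),
                       group = unname(sim$expr$sample_groups)),
            p("groups.tsv"))
  write_tsv(data.frame(feature_id = names(sim$expr$feature_lengths),
                       length = unname(sim$expr$feature_lengths)),
            p("lengths.tsv"))
  write_tsv(data.frame(sample = names(sim$expr$library_sizes),
                       mapped_reads = unname(sim$expr$library_sizes)),
            p("library_sizes.tsv"))
  if (nrow(sim$evidence)) write_tsv(sim$evidence, p("evidence.tsv"))
  write_tsv(sim$de, p("de_testis_vs_ovary.tsv"))
  utils::write.table(sim$orthologs, p("orthologs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  go_df <- data.frame(gene = names(sim$go$gene2terms),
                      terms = vapply(sim$go$gene2terms, paste,
                                     character(1), collapse = ";"))
  utils::write.table(go_df, p("go.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  for (t in names(sim$truth))
    write_tsv(sim$truth[[t]], p(paste0("truth_", t, ".tsv")))
  files <- list.files(dir, full.names = TRUE)
  invisible(stats::setNames(files, basename(files)))
}
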