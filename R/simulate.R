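#' Configuration for the synthetic study generator
#'
#' The generator emulates the downstream structure of a multi-tissue
#' insect RNA-seq lncRNA study: a chromosome-level genome with
#' protein-coding genes laid out in slots, planted lncRNA candidates of
#' the three genomic-context classes plus decoys for every filter, a
#' TE track with fixed overlap fractions, 21 expression samples over
#' 14 groups (9 tissues, two of them without replicates, and 5
#' developmental stages), a testis-vs-ovary differential-expression
#' table, and a second species with partially conserved gene order for
#' synteny analysis. Every output is a deterministic function of
#' `seed`.
#'
#' @param seed integer seed; identical seeds give identical studies.
#' @param n_chrom chromosomes per species.
#' @param n_pcg_per_chrom PCG slots per chromosome, recycled to
#'   `n_chrom` (one gene per 10-kb slot; each chromosome's length is
#'   `(slots + 1) * 10` kb). Unequal values give chromosomes of
#'   different sizes, so lncRNA counts co-vary with chromosome size.
#' @param gc genomic GC fraction for the random background.
#' @param counts named integer vector of planted candidate densities
#'   per 30 slots (scaled to each chromosome's slot count): `lnc_u`, `lnc_i`, `lnc_x` (true lncRNAs by class),
#'   `coding` (coding decoys: >= 300 nt ORF plus external coding
#'   evidence), `lowexpr` (RPKM_max < 1 decoys), `short` (< 200 nt
#'   decoys), `sense` (same-strand overlap decoys). Their total must
#'   not exceed `n_pcg_per_chrom`.
#' @param te_overlap_lnc,te_overlap_pcg fractions of true lncRNAs /
#'   PCGs given an exonic TE overlap (placement is deterministic, so
#'   the fractions are exact up to rounding).
#' @param tissue_specific_frac fraction of PCGs with a single dominant
#'   tissue (the rest are housekeeping-like).
#' @param lnc_specific_frac fraction of non-paired true lncRNAs with a
#'   dominant non-reproductive tissue.
#' @param testis_biased_lnc_frac,ovary_biased_lnc_frac fractions of
#'   true lncRNAs planted as testis- / ovary-dominant.
#' @param cis_frac fraction of intergenic lncRNAs sharing a latent
#'   expression profile with their nearest PCG.
#' @param cis_rho target Pearson correlation of planted cis pairs.
#' @param nb_dispersion negative-binomial dispersion of the counts
#'   (0 gives deterministic rounded means).
#' @param library_size total mapped reads per sample.
#' @param conserved_blocks number of 10-slot blocks per chromosome
#'   whose gene order species B preserves; the remaining slots are
#'   scattered across species B.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_chrom = 3,
                       n_pcg_per_chrom = c(40, 30, 20),
                       gc = 0.42,
                       counts = c(lnc_u = 8, lnc_i = 3, lnc_x = 3,
                                  coding = 5, lowexpr = 2, short = 1,
                                  sense = 2),
                       te_overlap_lnc = 0.5,
                       te_overlap_pcg = 0.4,
                       tissue_specific_frac = 0.3,
                       lnc_specific_frac = 0.4,
                       testis_biased_lnc_frac = 0.25,
                       ovary_biased_lnc_frac = 0.05,
                       cis_frac = 0.5,
                       cis_rho = 0.8,
                       nb_dispersion = 0.05,
                       library_size = 2e6,
                       conserved_blocks = 2) {
  n_pcg_per_chrom <- rep_len(n_pcg_per_chrom, n_chrom)
  stopifnot(all(sum(counts) * n_pcg_per_chrom / 30 <= n_pcg_per_chrom),
            te_overlap_lnc >= 0, te_overlap_lnc <= 1,
            te_overlap_pcg >= 0, te_overlap_pcg <= 1,
            cis_rho > 0, cis_rho <= 1, nb_dispersion >= 0)
  cfg <- as.list(environment())
  cfg$unit <- 10000L
  cfg$block_slots <- 10L
  cfg$tissues <- c("Ag", "Ma", "Fa", "Tes", "Ov", "Mhd", "Fhd", "Mmg", "Fmg")
  cfg$stages <- c("E1", "E4", "L5", "FP", "AF")
  cfg$replicates <- c(Ag = 2L, Ma = 1L, Fa = 1L, Tes = 2L, Ov = 2L,
                      Mhd = 2L, Fhd = 2L, Mmg = 2L, Fmg = 2L,
                      E1 = 1L, E4 = 1L, L5 = 1L, FP = 1L, AF = 1L)
  class(cfg) <- "sim_config"
  cfg
}

# stop-codon motif present in all three frames on both strands
# (it equals its own reverse complement)
STOP_MOTIF <- "TAAATAAATAATTATTTATTTA"

random_dna <- function(len, gc) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# random sequence guaranteed to hold no ORF of >= 300 nt on either
# strand: stop motifs every <= 70 random nt
safe_noncoding_seq <- function(len, gc = 0.42) {
  out <- character(0)
  have <- 0L
  while (have < len) {
    blk <- paste0(random_dna(70L, gc), STOP_MOTIF)
    out <- c(out, blk)
    have <- have + nchar(blk)
  }
  substr(paste(out, collapse = ""), 1L, len)
}

# sequence whose longest ORF is orf_nt (ATG + non-stop codons + TAA),
# padded to total_len with safe sequence
coding_decoy_seq <- function(total_len, orf_nt = 396L, gc = 0.42) {
  ncod <- orf_nt / 3L - 2L
  body <- paste(sample(c("GCA", "GAA", "CTG", "AAC", "GGT", "TTC"),
                       ncod, replace = TRUE), collapse = "")
  orf <- paste0("ATG", body, "TAA")
  paste0(orf, safe_noncoding_seq(total_len - nchar(orf), gc))
}

#' Generate the two species' genomes
#'
#' Random sequences at the configured GC content; one chromosome per
#' PCG-slot layout for each species. Gene order (the annotation layer)
#' is what species B shuffles, so both genomes are plain random
#' background here; planted transcript sequences are written in by
#' [generate_annotations()].
#'
#' @param cfg a [sim_config()].
#' @return list `a`, `b`: named character vectors of chromosome
#'   sequences.
#' @export
generate_genomes <- function(cfg) {
  set.seed(cfg$seed)
  lens <- (cfg$n_pcg_per_chrom + 1L) * cfg$unit
  mk <- function(prefix) {
    stats::setNames(
      vapply(seq_len(cfg$n_chrom), function(i) random_dna(lens[i], cfg$gc),
             character(1)),
      paste0(prefix, seq_len(cfg$n_chrom)))
  }
  list(a = mk("chrA"), b = mk("chrB"))
}

# deterministic candidate-to-slot assignment: intergenic lncRNAs are
# placed on a fixed stride of >= 3 slots (closer planted loci would be
# genuinely cross-linked by the 3-flanking-gene synteny rule, blurring
# the planted family truth); the remaining types are spread evenly
# over the leftover slots
slot_plan <- function(counts, n_slots) {
  plan <- rep(NA_character_, n_slots)
  n_u <- if ("lnc_u" %in% names(counts)) counts[["lnc_u"]] else 0L
  if (n_u > 0) {
    stride <- max(3L, floor(n_slots / n_u))
    u_slots <- seq(1L, by = stride, length.out = n_u)
    if (max(u_slots) > n_slots)
      stop("too many lnc_u candidates for the slot count")
    plan[u_slots] <- "lnc_u"
  }
  rest <- counts[setdiff(names(counts), "lnc_u")]
  inst <- data.frame(
    type = rep(names(rest), rest),
    key = unlist(lapply(rest, function(k) (seq_len(k) - 0.5) / k)),
    stringsAsFactors = FALSE)
  inst <- inst[order(inst$key, inst$type), ]
  free <- which(is.na(plan))
  if (nrow(inst) > length(free)) stop("more candidates than free slots")
  plan[free[seq_len(nrow(inst))]] <- inst$type
  plan
}

# exon offsets (relative to slot base, 0-based) per feature kind
slot_geometry <- function() {
  list(pcg = list(exons = rbind(c(1000L, 1799L), c(2600L, 3199L),
                                c(3400L, 3999L))),
       lnc_u = list(exons = rbind(c(5000L, 5399L), c(5600L, 5999L))),
       coding = list(exons = rbind(c(6000L, 6399L), c(6600L, 6999L))),
       lowexpr = list(exons = rbind(c(8000L, 8399L), c(8600L, 8999L))),
       short = list(exons = rbind(c(7000L, 7099L), c(7200L, 7249L))),
       lnc_i = list(exons = rbind(c(1850L, 2099L), c(2300L, 2549L))),
       lnc_x = list(exons = rbind(c(1100L, 1499L), c(1650L, 1999L))),
       sense = list(exons = rbind(c(1200L, 1599L), c(1700L, 2099L))))
}

#' Generate annotations, TE track, evidence table and truth
#'
#' Lays one PCG per 10-kb slot (alternating strands) on every
#' chromosome of species A, plants the configured candidates at fixed
#' in-slot offsets (intergenic, intron-contained, antisense-exon
#' overlapping, same-strand decoys), writes their sequences into the
#' genome (ORF-free for true lncRNAs, a >= 300 nt ATG ORF for coding
#' decoys), places TE records inside exons to hit the configured
#' overlap fractions exactly, and builds the species-B annotation by
#' copying the conserved blocks' gene order and scattering the rest.
#'
#' @param cfg a [sim_config()].
#' @param genomes output of [generate_genomes()].
#' @return list `ref_a`, `candidates_a`, `ref_b`, `lnc_b`
#'   ([annotation()]s), `te` (TE track data.frame), `evidence`
#'   (coding-evidence data.frame), `genomes` (sequence-edited), and
#'   `truth` (`transcripts`, `synteny` data.frames).
#' @export
generate_annotations <- function(cfg, genomes) {
  set.seed(cfg$seed + 1L)
  geo <- slot_geometry()
  unit <- cfg$unit
  gseq_a <- genomes$a
  conserved_slots <- cfg$conserved_blocks * cfg$block_slots

  pcg_ex <- list(); cand_ex <- list(); truth <- list()
  ev_sig <- list(c("cpc_coding"), c("cnci_coding"), c("blastx_hit"),
                 c("pfam_hit"),
                 c("cpc_coding", "cnci_coding", "blastx_hit", "pfam_hit"))
  ev_rows <- list()
  sig_i <- 0L

  for (c_i in seq_len(cfg$n_chrom)) {
    chrom <- paste0("chrA", c_i)
    n_slots <- cfg$n_pcg_per_chrom[c_i]
    scaled <- round(cfg$counts * n_slots / 30)
    names(scaled) <- names(cfg$counts)
    plan <- slot_plan(pmax(scaled, 0L), n_slots)
    for (s in seq_len(n_slots)) {
      base <- (s - 1L) * unit
      strand <- if (s %% 2L == 1L) "+" else "-"
      gid <- sprintf("PCG_%d_%02d", c_i, s)
      tid <- sprintf("mRNA_%d_%02d", c_i, s)
      pcg_ex[[length(pcg_ex) + 1L]] <- data.frame(
        transcript_id = tid, gene_id = gid, chrom = chrom,
        start = base + geo$pcg$exons[, 1] + 1L,
        end = base + geo$pcg$exons[, 2] + 1L,
        strand = strand, stringsAsFactors = FALSE)

      type <- plan[s]
      if (is.na(type)) next
      g <- geo[[type]]
      cand_strand <- switch(type,
                            lnc_x = if (strand == "+") "-" else "+",
                            sense = strand,
                            "+")
      ctid <- sprintf("TX_%d_%02d", c_i, s)
      cgid <- sprintf("LOC_%d_%02d", c_i, s)
      starts <- base + g$exons[, 1] + 1L
      ends <- base + g$exons[, 2] + 1L
      cand_ex[[length(cand_ex) + 1L]] <- data.frame(
        transcript_id = ctid, gene_id = cgid, chrom = chrom,
        start = starts, end = ends, strand = cand_strand,
        stringsAsFactors = FALSE)

      # write the planted sequence into the genome, exon by exon
      widths <- ends - starts + 1L
      total <- sum(widths)
      seq_planted <- if (type == "coding")
        coding_decoy_seq(total, gc = cfg$gc)
      else safe_noncoding_seq(total, cfg$gc)
      off <- 0L
      for (e in seq_along(starts)) {
        piece <- substr(seq_planted, off + 1L, off + widths[e])
        substr(gseq_a[chrom], starts[e], ends[e]) <- piece
        off <- off + widths[e]
      }

      if (type == "coding") {
        sig_i <- sig_i + 1L
        sig <- ev_sig[[(sig_i - 1L) %% length(ev_sig) + 1L]]
        row <- data.frame(transcript_id = ctid, cpc_coding = FALSE,
                          cnci_coding = FALSE, blastx_hit = FALSE,
                          pfam_hit = FALSE, stringsAsFactors = FALSE)
        row[, sig] <- TRUE
        ev_rows[[length(ev_rows) + 1L]] <- row
      }

      truth[[length(truth) + 1L]] <- data.frame(
        transcript_id = ctid, gene_id = cgid, chrom = chrom, slot = s,
        type = type,
        planted_code = switch(type, lnc_u = "u", lnc_i = "i",
                              lnc_x = "x", coding = "u", lowexpr = "u",
                              short = "u", sense = "sense"),
        is_lnc = type %in% c("lnc_u", "lnc_i", "lnc_x"),
        # a u-locus is syntenic iff its flanks reach into the conserved
        # region on both sides; at the last conserved slot the right
        # flank is already scattered
        conserved = type == "lnc_u" && s < conserved_slots,
        stringsAsFactors = FALSE)
    }
  }
  pcg_ex <- do.call(rbind, pcg_ex)
  cand_ex <- do.call(rbind, cand_ex)
  tx_truth <- do.call(rbind, truth)

  sizes_a <- stats::setNames((cfg$n_pcg_per_chrom + 1L) * unit,
                             paste0("chrA", seq_len(cfg$n_chrom)))
  ref_a <- annotation(pcg_ex, chrom_sizes = sizes_a)
  candidates_a <- annotation(cand_ex, chrom_sizes = sizes_a)

  # TE track: one record inside an exon of the first ceil(f * n)
  # true lncRNAs / PCGs (id order), TE classes cycled
  te_classes <- c("LINE", "SINE", "LTR", "DNA", "RC/Helitron", "Unknown")
  te <- list()
  lnc_ids <- sort(tx_truth$transcript_id[tx_truth$is_lnc])
  n_te_lnc <- ceiling(cfg$te_overlap_lnc * length(lnc_ids))
  for (j in seq_len(n_te_lnc)) {
    ex <- cand_ex[cand_ex$transcript_id == lnc_ids[j], ][1, ]
    # second half of the exon: clear of any reference exon overlap
    te[[length(te) + 1L]] <- data.frame(
      chrom = ex$chrom, start = ex$end - 60L, end = ex$end - 10L,
      te_class = te_classes[(j - 1L) %% length(te_classes) + 1L],
      stringsAsFactors = FALSE)
  }
  pcg_gids <- sort(unique(pcg_ex$gene_id))
  n_te_pcg <- ceiling(cfg$te_overlap_pcg * length(pcg_gids))
  for (j in seq_len(n_te_pcg)) {
    ex <- pcg_ex[pcg_ex$gene_id == pcg_gids[j], ]
    ex <- ex[nrow(ex), ]  # last exon: no candidate overlaps it
    te[[length(te) + 1L]] <- data.frame(
      chrom = ex$chrom, start = ex$start + 50L, end = ex$start + 100L,
      te_class = te_classes[(j - 1L) %% length(te_classes) + 1L],
      stringsAsFactors = FALSE)
  }
  te <- do.call(rbind, te)

  evidence <- if (length(ev_rows)) do.call(rbind, ev_rows)
              else data.frame()

  # ---- species B: conserved blocks keep gene order, the rest scatter
  gseq_b <- genomes$b
  a_genes <- unique(pcg_ex[, c("gene_id", "chrom")])
  a_genes$slot <- as.integer(sub(".*_(\\d+)$", "\\1", a_genes$gene_id))
  a_genes$chrom_i <- as.integer(sub("chrA", "", a_genes$chrom))
  cons <- a_genes[a_genes$slot <= conserved_slots, ]
  rear <- a_genes[a_genes$slot > conserved_slots, ]
  # reverse then stride-interleave the rearranged genes so A-adjacent
  # genes land far apart in B and no gene keeps its mirror position
  m <- nrow(rear)
  stride <- 7L
  perm <- as.vector(t(matrix(c(seq_len(m), rep(NA, stride * ceiling(m / stride) - m)),
                             ncol = stride)))
  perm <- perm[!is.na(perm)]
  rear <- rear[order(rear$chrom_i, rear$slot, decreasing = TRUE), ][perm, ]

  b_ex <- list(); b_lnc_ex <- list(); syn_truth <- list()
  b_of <- function(a_gid) sub("^PCG_", "BPC_", a_gid)
  rear_cursor <- 1L
  for (c_i in seq_len(cfg$n_chrom)) {
    chrom <- paste0("chrB", c_i)
    for (s in seq_len(cfg$n_pcg_per_chrom[c_i])) {
      if (s <= conserved_slots) {
        a_gid <- cons$gene_id[cons$chrom_i == c_i & cons$slot == s]
      } else {
        if (rear_cursor > nrow(rear)) next
        a_gid <- rear$gene_id[rear_cursor]
        rear_cursor <- rear_cursor + 1L
      }
      base <- (s - 1L) * unit
      strand <- if (s %% 2L == 1L) "+" else "-"
      b_ex[[length(b_ex) + 1L]] <- data.frame(
        transcript_id = sub("^PCG_", "BmRNA_", a_gid),
        gene_id = b_of(a_gid), chrom = chrom,
        start = base + slot_geometry()$pcg$exons[, 1] + 1L,
        end = base + slot_geometry()$pcg$exons[, 2] + 1L,
        strand = strand, stringsAsFactors = FALSE)
    }
  }
  # B lncRNAs: conserved u-loci at the matching slot; rearranged u-loci
  # next to wherever their A-slot neighbour gene landed
  u_truth <- tx_truth[tx_truth$type == "lnc_u", ]
  b_ex_df <- do.call(rbind, b_ex)
  b_ex_df$slot <- as.integer(sub(".*_(\\d+)$", "\\1", b_ex_df$gene_id))
  b_ex_df$a_chrom_i <- as.integer(sub("^BPC_(\\d+)_.*", "\\1", b_ex_df$gene_id))
  for (r in seq_len(nrow(u_truth))) {
    c_i <- as.integer(sub("chrA", "", u_truth$chrom[r]))
    s <- u_truth$slot[r]
    host_gid <- b_of(sprintf("PCG_%d_%02d", c_i, s))
    host <- b_ex_df[b_ex_df$gene_id == host_gid, ][1, ]
    if (is.na(host$chrom)) next
    host_chr_i <- as.integer(sub("chrB", "", host$chrom))
    host_slot <- floor((host$start - 1L) / unit) + 1L
    base <- (host_slot - 1L) * unit
    blid <- sprintf("BLOC_%d_%02d", c_i, s)
    b_lnc_ex[[length(b_lnc_ex) + 1L]] <- data.frame(
      transcript_id = sprintf("BTX_%d_%02d", c_i, s), gene_id = blid,
      chrom = paste0("chrB", host_chr_i),
      start = base + slot_geometry()$lnc_u$exons[, 1] + 1L,
      end = base + slot_geometry()$lnc_u$exons[, 2] + 1L,
      strand = "+", stringsAsFactors = FALSE)
    syn_truth[[length(syn_truth) + 1L]] <- data.frame(
      locus_a = u_truth$gene_id[r], locus_b = blid,
      syntenic = u_truth$conserved[r], stringsAsFactors = FALSE)
  }
  b_ex_df$slot <- b_ex_df$a_chrom_i <- NULL
  sizes_b <- stats::setNames((cfg$n_pcg_per_chrom + 1L) * unit,
                             paste0("chrB", seq_len(cfg$n_chrom)))
  ref_b <- annotation(b_ex_df, chrom_sizes = sizes_b)
  lnc_b <- annotation(do.call(rbind, b_lnc_ex), chrom_sizes = sizes_b)

  orthologs <- data.frame(gene_a = a_genes$gene_id,
                          gene_b = b_of(a_genes$gene_id),
                          group_id = sprintf("OG%04d",
                                             seq_len(nrow(a_genes))),
                          stringsAsFactors = FALSE)

  list(ref_a = ref_a, candidates_a = candidates_a, ref_b = ref_b,
       lnc_b = lnc_b, te = te, evidence = evidence,
       orthologs = orthologs,
       genomes = list(a = gseq_a, b = gseq_b),
       truth = list(transcripts = tx_truth,
                    synteny = do.call(rbind, syn_truth)))
}
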