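mk_hits <- function(q, s, e) {
  data.frame(qseqid = q, sseqid = s, pident = 90, length = 100,
             mismatch = 0, gapopen = 0, qstart = 1, qend = 100,
             sstart = 1, send = 100, evalue = e, bitscore = 200)
}

test_that("BLAST summaries count distinct queries once and respect the cutoff", {
  hits <- mk_hits(c("q1", "q1", "q1"), c("s1", "s2", "s3"),
                  c(1e-5, 1e-4, 1e-20))
  expect_equal(summarize_blast(hits, 1e-3)$n_query_hit, 1L)
  expect_equal(summarize_blast(hits, 1e-30)$n_query_hit, 0L)
  mixed <- mk_hits(c("q1", "q2", "q2", "q3"), c("s1", "s1", "s2", "s2"),
                   c(1e-5, 1e-12, 0.5, 1e-11))
  s3 <- summarize_blast(mixed, 1e-3, count_targets = TRUE)
  s10 <- summarize_blast(mixed, 1e-10, count_targets = TRUE)
  # brute-force distinct counts
  keep <- mixed[mixed$evalue <= 1e-3, ]
  expect_equal(s3$n_query_hit, length(unique(keep$qseqid)))
  expect_equal(s3$n_target_hit, length(unique(keep$sseqid)))
  # monotone in the cutoff
  expect_lte(s10$n_query_hit, s3$n_query_hit)
  expect_lte(s10$n_target_hit, s3$n_target_hit)
  expect_warning(summarize_blast(mixed, 1e-3, query_ids = "q1"),
                 "not in the query set")
})

test_that("relative decrease reproduces the cutoff-shrinkage arithmetic", {
  expect_equal(relative_decrease(15, 11), 26.67)
  expect_equal(relative_decrease(74, 58), 21.62)
  expect_equal(relative_decrease(8, 8), 0)
  expect_equal(relative_decrease(8, 0), 100)
  expect_true(is.na(relative_decrease(0, 0)))
})

test_that("neighbourhoods take the k nearest genes per side, midpoint rule for overlaps", {
  genes <- data.frame(gene_id = paste0("g", 1:6), chrom = "c1",
                      strand = "+",
                      start = seq(1000, 51000, by = 10000),
                      end = seq(3000, 53000, by = 10000))
  locus <- list(gene_id = "L", chrom = "c1", start = 24000, end = 25000)
  nb <- build_neighborhood(locus, genes)
  expect_equal(nb$left, c("g3", "g2", "g1"))
  expect_equal(nb$right, c("g4", "g5", "g6"))
  # before the first gene: left empty
  nb2 <- build_neighborhood(list(gene_id = "L", chrom = "c1",
                                 start = 100, end = 200), genes)
  expect_equal(nb2$left, character(0))
  expect_equal(nb2$right, c("g1", "g2", "g3"))
  # overlapping gene assigned by midpoint
  ov <- list(gene_id = "L", chrom = "c1", start = 21500, end = 24000)
  nb3 <- build_neighborhood(ov, genes)  # g3 midpoint 22000 < locus 22750
  expect_equal(nb3$left[1], "g3")
  # unknown chromosome: empty neighbourhood
  nb4 <- build_neighborhood(list(gene_id = "L", chrom = "c9",
                                 start = 1, end = 2), genes)
  expect_equal(length(nb4$left) + length(nb4$right), 0L)
})

test_that("syntenic pairs need 3 shared groups with support on both sides", {
  orth <- data.frame(gene_a = paste0("a", 1:6),
                     gene_b = paste0("b", 1:6),
                     group_id = paste0("OG", 1:6))
  nA <- list(left = c("a3", "a2", "a1"), right = c("a4", "a5", "a6"))
  nB <- list(left = c("b3", "b2", "b1"), right = c("b4", "b5", "b6"))
  full <- syntenic_pair(nA, nB, orth)
  expect_true(full$accepted)
  expect_equal(length(full$shared_groups), 6L)
  # only two orthologous flankers
  nB2 <- list(left = c("b3"), right = c("b4"))
  expect_false(syntenic_pair(nA, nB2, orth)$accepted)
  # three shared groups but all on one side of species B
  nB3 <- list(left = c("b1", "b2", "b3"), right = "bX")
  expect_false(syntenic_pair(nA, nB3, orth)$accepted)
  # symmetric under swapping the species (with the maps swapped)
  orth_sw <- data.frame(gene_a = orth$gene_b, gene_b = orth$gene_a,
                        group_id = orth$group_id)
  expect_equal(syntenic_pair(nB, nA, orth_sw)$accepted, full$accepted)
  # tandem duplicates collapse into one group
  orth_dup <- rbind(orth,
                    data.frame(gene_a = "a7", gene_b = "b7",
                               group_id = "OG1"))
  nA2 <- list(left = c("a1", "a7"), right = c("a4"))
  nB4 <- list(left = c("b1", "b7"), right = c("b4"))
  sp <- syntenic_pair(nA2, nB4, orth_dup)
  expect_false(sp$accepted)  # OG1 counted once: only 2 distinct shared
})

test_that("families are the connected components of the accepted-pair graph", {
  pairs <- data.frame(locus_a = c("A1", "A2", "A3"),
                      locus_b = c("B1", "B1", "B9"))
  fam <- build_families(pairs)
  expect_equal(unname(fam$summary["n_families"]), 2L)
  first <- fam$families[fam$families$family_id ==
    fam$families$family_id[fam$families$locus_id == "A1"], ]
  expect_setequal(first$locus_id, c("A1", "A2", "B1"))
  expect_equal(unname(build_families(pairs[0, ])$summary["n_families"]), 0L)
  # random small graphs match the transitive-closure oracle
  set.seed(14)
  for (rep in 1:5) {
    p <- data.frame(locus_a = paste0("A", sample(8, 12, TRUE)),
                    locus_b = paste0("B", sample(8, 12, TRUE)))
    fam2 <- build_families(p)
    want <- oracle_components(data.frame(paste0("A|", p$locus_a),
                                         paste0("B|", p$locus_b)))
    expect_equal(unname(fam2$summary["n_families"]), length(want))
    got_sets <- unname(lapply(split(
      paste0(fam2$families$species, "|", fam2$families$locus_id),
      fam2$families$family_id), sort))
    want_sets <- unname(lapply(want, sort))
    expect_true(all(got_sets %in% want_sets) &&
                all(want_sets %in% got_sets))
  }
})

test_that("planted conserved blocks are recovered as families, rearranged loci are not", {
  sim <- get_study()
  tr <- sim$truth$transcripts
  u <- subset_annotation(sim$candidates_a,
                         tr$transcript_id[tr$type == "lnc_u"])
  fam <- synteny_families(u, sim$lnc_b, sim$ref_a, sim$ref_b,
                          sim$orthologs)
  st <- sim$truth$synteny
  want <- paste(st$locus_a, st$locus_b)[st$syntenic]
  expect_setequal(paste(fam$pairs$locus_a, fam$pairs$locus_b), want)
  expect_equal(unname(fam$summary["n_families"]), sum(st$syntenic))
  # loci in rearranged regions belong to no family
  lost <- st$locus_a[!st$syntenic]
  expect_false(any(lost %in% fam$families$locus_id))
})
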