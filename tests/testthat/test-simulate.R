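test_that("the generator is fully deterministic under a seed", {
  s1 <- simulate_study(sim_config(seed = 5))
  s2 <- simulate_study(sim_config(seed = 5))
  expect_identical(as.character(s1$genomes$a), as.character(s2$genomes$a))
  expect_identical(s1$expr$counts, s2$expr$counts)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$te, s2$te)
  s3 <- simulate_study(sim_config(seed = 6))
  expect_false(identical(as.character(s1$genomes$a),
                         as.character(s3$genomes$a)))
})

test_that("generated genomes hit the configured GC content", {
  cfg <- sim_config(seed = 3, n_chrom = 1, n_pcg_per_chrom = 49, gc = 0.5)
  g <- generate_genomes(cfg)
  expect_equal(nchar(g$a[[1]]), 500000L)
  expect_lt(abs(gc_content(g$a[[1]]) - 50), 1)
  cfg2 <- sim_config(seed = 3, n_chrom = 1, n_pcg_per_chrom = 49,
                     gc = 0.3)
  expect_lt(abs(gc_content(generate_genomes(cfg2)$a[[1]]) - 30), 1)
})

test_that("planted candidates carry their intended geometry", {
  sim <- get_study()
  tr <- sim$truth$transcripts
  tx <- sim$candidates_a$transcripts
  # every planted class is classified as planted (by construction)
  codes <- classify_transcripts(sim$candidates_a, sim$ref_a)
  m <- merge(codes, tr, by = "transcript_id")
  expect_equal(mean(m$code == m$planted_code), 1)
  # short decoys are under 200 nt, everything else at least 200
  short <- tx$exonic_length[tx$transcript_id %in%
                            tr$transcript_id[tr$type == "short"]]
  expect_true(all(short < 200))
  # coding decoys hold a >= 300 nt ORF; true lncRNAs never do
  for (id in tr$transcript_id[tr$type == "coding"])
    expect_gte(longest_orf(spliced_sequence(sim$candidates_a, id,
                                            sim$genomes$a)), 300)
  for (id in tr$transcript_id[tr$is_lnc])
    expect_lt(longest_orf(spliced_sequence(sim$candidates_a, id,
                                           sim$genomes$a)), 300)
})

test_that("TE placement hits the configured overlap fractions exactly", {
  sim <- get_study()
  tr <- sim$truth$transcripts
  lnc <- subset_annotation(sim$candidates_a,
                           tr$transcript_id[tr$is_lnc])
  ov <- te_overlap(lnc, sim$ref_a, sim$te)
  n_lnc <- sum(tr$is_lnc)
  expect_equal(sum(ov$flags_a),
               ceiling(sim$config$te_overlap_lnc * n_lnc))
  n_pcg <- length(unique(sim$ref_a$transcripts$gene_id))
  expect_equal(sum(ov$flags_b),
               ceiling(sim$config$te_overlap_pcg * n_pcg))
})

test_that("dispersion zero makes observed RPKM reproduce the planted means", {
  cfg <- sim_config(seed = 9, nb_dispersion = 0)
  sim <- simulate_study(cfg)
  prof_obs <- average_replicates(sim$expr)
  common <- intersect(rownames(prof_obs), rownames(sim$profile))
  # rounding of the expected counts is the only distortion
  mu_counts <- sim$profile[common, colnames(prof_obs)] *
    sim$expr$feature_lengths[common] * cfg$library_size / 1e9
  big <- mu_counts > 20
  rel <- abs(prof_obs[common, ] - sim$profile[common, colnames(prof_obs)]) /
    sim$profile[common, colnames(prof_obs)]
  expect_lt(max(rel[big]), 0.05)
})

test_that("planted cis pairs show the target correlation in the planted profiles", {
  sim <- get_study()
  pt <- sim$truth$pairs
  on <- pt[pt$rho > 0, ]
  r <- vapply(seq_len(nrow(on)), function(i)
    pearson_pair(sim$profile[on$anchor_tx[i], ],
                 sim$profile[on$partner_gene[i], ])$pcc, numeric(1))
  expect_lt(abs(mean(r) - sim$config$cis_rho), 0.1)
})

test_that("study files round-trip through the package readers", {
  sim <- get_study()
  dir <- withr::local_tempdir()
  files <- write_study_files(sim, dir)
  g <- read_genome_fasta(files[["genome_a.fa"]])
  expect_identical(as.character(g), as.character(sim$genomes$a))
  cand <- read_gtf(files[["candidates_a.gtf"]])
  expect_equal(cand$transcripts[, names(cand$transcripts) != "biotype"],
               sim$candidates_a$transcripts[,
                 names(sim$candidates_a$transcripts) != "biotype"])
  te <- read_te_track(files[["te.bed"]])
  expect_equal(te, sim$te, ignore_attr = TRUE)
  counts <- read_counts_table(files[["counts.tsv"]])
  expect_equal(counts, sim$expr$counts)
  orth <- read_ortholog_table(files[["orthologs.tsv"]])
  expect_equal(orth, sim$orthologs, ignore_attr = TRUE)
})
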