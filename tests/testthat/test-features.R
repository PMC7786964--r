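test_that("size statistics pool exon and intron lengths correctly", {
  ann <- mk_ann(mk_tx("t1", list(c(1, 100), c(201, 400))),
                mk_tx("t2", list(c(1000, 1499))))
  st <- size_stats(ann)
  expect_setequal(st$transcript_length, c(300L, 500L))
  expect_setequal(st$exon_length, c(100L, 200L, 500L))
  expect_equal(st$intron_length, 100L)
  expect_equal(st$summary$median[st$summary$metric == "transcript_length"],
               400)
  one <- size_stats(mk_ann(mk_tx("t", list(c(1, 60)))))
  expect_equal(one$summary$median[1], 60)
  # pooled medians equal a brute-force sort on a random set
  set.seed(12)
  r <- random_annotation(30)
  st2 <- size_stats(r)
  v <- sort(st2$exon_length)
  expect_equal(st2$summary$median[st2$summary$metric == "exon_length"],
               stats::median(v))
})

test_that("GC content excludes ambiguity codes from the denominator", {
  expect_equal(gc_content("ACGT"), 50)
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("NNAT"), 0)
  expect_true(is.na(gc_content("NNNN")))
  expect_equal(gc_content(c("ACGT", "GGCC")), c(50, 100))
})

test_that("splice-site context is strand-corrected and canonical introns counted", {
  # + strand: exon 11..20, intron GTAAG...TTTAG (21..35), exon 36..45
  intron <- "GTAAGCCCCCTTTAG"
  gseq <- paste0(strrep("A", 10), "CCCCCCCCCC", intron, "GGGGGGGGGG",
                 strrep("A", 10))
  g <- toy_genome(c1 = gseq)
  ann <- mk_ann(mk_tx("t", list(c(11, 20), c(36, 45))))
  ctx <- splice_site_context(ann, g, flank = 4)
  expect_equal(ctx$n_introns, 1L)
  expect_equal(ctx$canonical_fraction, 1)
  expect_equal(ctx$donor["G", "I1"], 1)
  expect_equal(ctx$donor["T", "I2"], 1)
  expect_equal(ctx$acceptor["A", "I-2"], 1)
  expect_equal(ctx$acceptor["G", "I-1"], 1)
  expect_equal(ctx$acceptor["G", "A1"], 1)
  expect_true(all(abs(colSums(ctx$donor) - 1) < 1e-12))

  # the reverse-complemented genome with flipped strands gives the
  # same tallies
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(gseq)))
  L <- nchar(gseq)
  flip <- mk_ann(mk_tx("t", list(c(L - 45 + 1, L - 36 + 1),
                                 c(L - 20 + 1, L - 11 + 1)),
                       strand = "-"))
  ctx2 <- splice_site_context(flip, toy_genome(c1 = rc), flank = 4)
  expect_equal(ctx2$donor, ctx$donor)
  expect_equal(ctx2$acceptor, ctx$acceptor)
  expect_equal(ctx2$canonical_fraction, 1)
})

test_that("TE overlap is exon-based and matches brute-force intersection", {
  lnc <- mk_ann(mk_tx("l1", list(c(100, 200), c(301, 400))),
                mk_tx("l2", list(c(1000, 1100))))
  pcg <- mk_ann(mk_tx("p1", list(c(2000, 2200))))
  te <- data.frame(chrom = "c1", start = c(150, 250, 2100),
                   end = c(160, 260, 2120),
                   te_class = c("LINE", "SINE", "LINE"))
  ov <- te_overlap(lnc, pcg, te)
  expect_equal(unname(ov$flags_a), c(TRUE, FALSE))  # TE at 250 is intronic
  expect_equal(unname(ov$flags_b), TRUE)
  expect_equal(ov$table["overlap", "a"], 1)
  # span mode picks up the intronic TE too
  ov_span <- te_overlap(lnc, pcg, te, mode = "span")
  expect_equal(unname(ov_span$flags_a), c(TRUE, FALSE))
  expect_true(all(c(1, 2) %in% ov_span$hits_a$te_index))
  # brute force over all (exon, record) pairs on a random set
  set.seed(13)
  r <- random_annotation(25, chroms = "c1")
  rte <- data.frame(chrom = "c1",
                    start = sample(1:5000, 15),
                    end = 0, te_class = "LINE")
  rte$end <- rte$start + sample(10:200, 15, replace = TRUE)
  flags <- te_overlap(r, r, rte)$flags_a
  for (id in names(flags)) {
    ex <- r$exons[r$exons$transcript_id == id, ]
    brute <- any(vapply(seq_len(nrow(rte)), function(k)
      any(ex$start <= rte$end[k] & ex$end >= rte$start[k]), logical(1)))
    expect_equal(unname(flags[id]), brute, info = id)
  }
  # empty TE track: all false, test skipped
  empty <- te_overlap(lnc, pcg, te[0, ])
  expect_false(any(empty$flags_a))
  expect_true(is.na(empty$test$p_value))
})

test_that("TE class composition counts overlapped records, not features", {
  hits <- data.frame(feature_id = c("l1", "l1", "l2"),
                     te_index = c(1, 2, 3),
                     te_class = c("LINE", "LINE", "SINE"))
  comp <- te_class_composition(hits)
  expect_equal(comp$n[comp$te_class == "LINE"], 2L)
  expect_equal(sum(comp$pct), 100)
  expect_equal(nrow(te_class_composition(hits[0, ])), 0L)
})

test_that("chromosome distribution correlates counts with size and PCG number", {
  sizes <- c(c1 = 1000, c2 = 2000, c3 = 3000, c4 = 4000, c5 = 5000)
  ex <- do.call(rbind, lapply(1:5, function(i) {
    k <- i  # counts exactly proportional to size
    do.call(rbind, lapply(seq_len(k), function(j)
      mk_tx(sprintf("t%d_%d", i, j), list(c(j * 10, j * 10 + 5)),
            chrom = paste0("c", i))))
  }))
  lnc <- annotation(ex, chrom_sizes = sizes)
  ref <- annotation(ex, chrom_sizes = sizes)  # same counts as "PCGs"
  cd <- chromosome_distribution(lnc, ref)
  expect_equal(cd$r_size, 1)
  expect_equal(cd$r_pcg, 1)
  # anti-proportional counts give a negative correlation
  ex2 <- do.call(rbind, lapply(1:5, function(i) {
    k <- 6 - i
    do.call(rbind, lapply(seq_len(k), function(j)
      mk_tx(sprintf("t%d_%d", i, j), list(c(j * 10, j * 10 + 5)),
            chrom = paste0("c", i))))
  }))
  cd2 <- chromosome_distribution(annotation(ex2, chrom_sizes = sizes), ref)
  expect_lt(cd2$r_size, 0)
  # r agrees with the covariance-formula oracle
  expect_equal(cd2$r_size,
               oracle_pearson(cd2$counts$n_lnc, cd2$counts$size),
               tolerance = 1e-12)
})
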