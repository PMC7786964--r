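test_that("longest_orf handles canonical and edge cases", {
  expect_equal(longest_orf("ATGAAATAG"), 9L)
  expect_equal(longest_orf("CCCCCC"), 0L)
  expect_equal(longest_orf(""), 0L)
  # stop-less ORF runs to the last complete codon
  expect_equal(longest_orf("ATGAAAAA"), 6L)
  # ATG in a shifted frame
  expect_equal(longest_orf("CATGAAATAA"), 9L)
})

test_that("longest_orf equals the exhaustive start-stop oracle on random sequences", {
  set.seed(7)
  for (rep in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 300,
                      replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
               collapse = "")
    expect_equal(longest_orf(s), oracle_orf(s), info = paste("rep", rep))
  }
  # and on a 1-kb sequence
  s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
             collapse = "")
  expect_equal(longest_orf(s), oracle_orf(s))
})

test_that("spliced_sequence concatenates exons and strand-corrects", {
  g <- toy_genome(c1 = "AAACCCGGGTTTACGTACGT")
  plus <- mk_ann(mk_tx("p", list(c(1, 3), c(7, 9))))
  expect_equal(spliced_sequence(plus, "p", g), "AAAGGG")
  minus <- mk_ann(mk_tx("m", list(c(13, 15)), strand = "-"))
  # genome ACG -> reverse complement CGT
  expect_equal(spliced_sequence(minus, "m", g), "CGT")
  n <- mk_ann(mk_tx("n", list(c(1, 4))))
  gn <- toy_genome(c1 = "ANNT")
  expect_equal(spliced_sequence(n, "n", gn), "ANNT")
  oob <- mk_ann(mk_tx("o", list(c(15, 30))))
  expect_error(spliced_sequence(oob, "o", g), "out of chromosome bounds")
})

test_that("the filter cascade removes exactly the planted decoys", {
  sim <- get_study()
  tr <- sim$truth$transcripts
  codes <- classify_transcripts(sim$candidates_a, sim$ref_a)
  keep <- codes[codes$code %in% c("u", "i", "x"), ]
  res <- apply_filter_cascade(
    subset_annotation(sim$candidates_a, keep$transcript_id), keep,
    sim$genomes$a, sim$evidence, sim$expr)
  planted <- sort(tr$transcript_id[tr$is_lnc])
  got <- sort(res$records$transcript_id)
  expect_identical(got, planted)   # precision = recall = 1
  # survivor counts never increase along the cascade
  expect_true(all(diff(res$report$n_surviving) <= 0))
  expect_true(all(res$report$n_surviving <= res$report$n_input))
  # every decoy type fails its designated criterion
  prov <- merge(res$provenance, tr[, c("transcript_id", "type")])
  expect_true(all(!prov$pass_a[prov$type == "short"]))
  expect_true(all(!prov$pass_f[prov$type == "lowexpr"]))
  expect_true(all(!prov$pass_c[prov$type == "coding"]))
  expect_true(all(prov$pass_b & prov$pass_d & prov$pass_e |
                  prov$type == "coding"))
})

test_that("criteria b-e commute: the survivor set ignores filter order", {
  sim <- get_study()
  codes <- classify_transcripts(sim$candidates_a, sim$ref_a)
  keep <- codes[codes$code %in% c("u", "i", "x"), ]
  res <- apply_filter_cascade(
    subset_annotation(sim$candidates_a, keep$transcript_id), keep,
    sim$genomes$a, sim$evidence, sim$expr)
  prov <- res$provenance
  # survivors = conjunction of the six flags, so any permutation of
  # the independent predicates yields the same set
  all_pass <- prov$pass_a & prov$pass_e & prov$pass_c & prov$pass_b &
    prov$pass_d & prov$pass_f
  expect_setequal(prov$transcript_id[all_pass], res$records$transcript_id)
})

test_that("cascade edge cases: short transcripts and missing expression", {
  g <- toy_genome(c1 = paste(rep("ACGT", 200), collapse = ""))
  ann <- mk_ann(mk_tx("t1", list(c(1, 80), c(101, 170))),       # 150 nt
                mk_tx("t2", list(c(201, 320), c(401, 500))))    # 220 nt
  codes <- data.frame(transcript_id = c("t1", "t2"), code = "u")
  expect_warning(
    res <- apply_filter_cascade(ann, codes, g, NULL, NULL),
    "rpkm_max")
  expect_equal(nrow(res$records), 0L)
  prov <- res$provenance
  expect_false(prov$pass_a[prov$transcript_id == "t1"])
  expect_true(prov$pass_a[prov$transcript_id == "t2"])
  expect_equal(prov$rpkm_max, c(0, 0))
  expect_error(
    apply_filter_cascade(ann, data.frame(transcript_id = "t1",
                                         code = "sense"), g),
    "codes u/i/x only")
})

test_that("composition percentages use half-up rounding on class counts", {
  tab <- summarize_composition(c(lincRNA = 6295, ilncRNA = 281,
                                 lncNAT = 3299))
  expect_equal(tab$pct[tab$class == "lincRNA"], 63.75)
  expect_equal(tab$pct[tab$class == "lncNAT"], 33.41)
  expect_equal(tab$pct[tab$class == "ilncRNA"], 2.85)
  one <- summarize_composition(c(lincRNA = 7))
  expect_equal(one$pct, 100)
  expect_equal(summarize_composition(c(a = 1, b = 2))$pct, c(33.33, 66.67))
  expect_equal(nrow(summarize_composition(data.frame(class = character()))),
               0L)
})
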