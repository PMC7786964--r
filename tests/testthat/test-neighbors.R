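test_that("neighbour finding respects the 10-kb inclusive span gap", {
  mk_gene <- function(id, s, e, strand = "+")
    mk_tx(id, list(c(s, e)), strand = strand, gene = id)
  anchors <- mk_ann(mk_gene("L1", 1000, 2000))
  pcg <- mk_ann(mk_gene("g_in", 12000, 13000),       # gap 9999
                mk_gene("g_at", 12001, 13000),       # gap 10000
                mk_gene("g_out", 12002, 13100),      # gap 10001
                mk_gene("g_nest", 1200, 1400, "-"))  # nested
  pairs <- find_neighbors(anchors, pcg)
  expect_setequal(pairs$partner_id, c("g_in", "g_at", "g_nest"))
  nest <- pairs[pairs$partner_id == "g_nest", ]
  expect_true(nest$overlapping)
  expect_equal(nest$distance, 0L)
  expect_equal(nest$orientation, "opposite")
  expect_equal(pairs$distance[pairs$partner_id == "g_in"], 9999L)
  # brute-force all-pairs scan on a random layout
  set.seed(15)
  a <- random_annotation(15, chroms = "c1")
  b <- random_annotation(15, chroms = "c1")
  got <- find_neighbors(a, b, max_dist = 500)
  ga <- a$transcripts; gb <- b$transcripts
  brute <- 0L
  for (i in seq_len(nrow(ga))) for (j in seq_len(nrow(gb))) {
    gap <- max(ga$start[i], gb$start[j]) - min(ga$end[i], gb$end[j]) - 1L
    if (gap <= 500 && ga$gene_id[i] != gb$gene_id[j]) brute <- brute + 1L
  }
  expect_equal(nrow(got), brute)
  # anchors are never paired with themselves
  self <- find_neighbors(a, a, max_dist = 500)
  expect_false(any(self$anchor_id == self$partner_id))
})

test_that("pair correlations follow the covariance formula and exclude flat vectors", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(pearson_pair(x, 2 * x)$pcc, 1)
  expect_equal(pearson_pair(x, -x)$pcc, -1)
  set.seed(16)
  y <- stats::rnorm(5)
  expect_equal(pearson_pair(x, y)$pcc, oracle_pearson(x, y),
               tolerance = 1e-12)
  flat <- pearson_pair(rep(2, 5), x)
  expect_true(is.na(flat$pcc))
})

test_that("cis candidates use a strict |PCC| threshold with sign tallies", {
  pairs <- data.frame(anchor_id = letters[1:5], partner_id = LETTERS[1:5],
                      pcc = c(0.5, 0.51, -0.61, NA, 0.2))
  cis <- call_cis_candidates(pairs)
  expect_setequal(cis$candidates$anchor_id, c("b", "c"))
  expect_equal(cis$n_positive, 1L)
  expect_equal(cis$n_negative, 1L)
})

test_that("strata comparisons run the exact rank-sum on small groups", {
  lnc <- data.frame(pcc = c(0.1, 0.2), overlapping = FALSE,
                    orientation = "same")
  pcg <- data.frame(pcc = c(0.3, 0.4), overlapping = FALSE,
                    orientation = "same")
  out <- compare_strata(lnc, pcg, strata = c("all", "overlapping"))
  expect_equal(out$p[out$stratum == "all"], 1 / 3, tolerance = 1e-12)
  expect_true(is.na(out$p[out$stratum == "overlapping"]))
  # identical distributions: p = 1 on a symmetric toy
  same <- compare_strata(lnc, lnc, strata = "all")
  expect_equal(same$p, 1)
})

test_that("planted correlated pairs are recovered and independent pairs mostly are not", {
  pp <- simulate_pair_profiles(200, 0.8, seed = 11)
  r <- vapply(seq_len(200), function(i)
    pearson_pair(pp$x[i, ], pp$y[i, ])$pcc, numeric(1))
  expect_lt(abs(mean(r) - 0.8), 0.1)
  expect_gte(mean(abs(r) > 0.5), 0.8)
  p0 <- simulate_pair_profiles(400, 0, seed = 12)
  r0 <- vapply(seq_len(400), function(i)
    pearson_pair(p0$x[i, ], p0$y[i, ])$pcc, numeric(1))
  expect_lte(mean(abs(r0) > 0.5), 0.1)
})

test_that("GO enrichment reproduces the hypergeometric closed forms", {
  bg <- sprintf("g%03d", 1:100)
  go <- stats::setNames(rep(list("T0"), 5), bg[1:5])
  res <- go_enrichment(bg[1:5], bg, go)
  expect_equal(res$p, 1 / choose(100, 5), tolerance = 1e-12)
  expect_equal(res$p, oracle_hyper_p(5, 5, 5, 100), tolerance = 1e-12)
  expect_equal(res$q, res$p)  # single tested term
  # query = background: every p is 1
  go2 <- lapply(stats::setNames(bg, bg), function(g) "T0")
  res2 <- go_enrichment(bg, bg, go2)
  expect_true(all(res2$p == 1))
  expect_error(go_enrichment("zz", bg, go), "subset")
  # random small instances against the binomial-coefficient oracle
  set.seed(17)
  for (rep in 1:5) {
    N <- 40; K <- sample(3:10, 1); n <- sample(5:15, 1)
    genes <- sprintf("x%02d", 1:N)
    ann <- lapply(stats::setNames(genes, genes), function(g) character())
    for (g in sample(genes, K)) ann[[g]] <- "T1"
    q <- sample(genes, n)
    res3 <- go_enrichment(q, genes, ann)
    k <- sum(q %in% names(ann)[vapply(ann, length, 1L) > 0])
    row <- res3[res3$term == "T1", ]
    expect_equal(row$k, k)
    expect_equal(row$p, oracle_hyper_p(k, K, n, N), tolerance = 1e-10)
  }
})

test_that("the planted GO term ranks first for the designated gene set", {
  sim <- get_study()
  bg <- unique(sim$ref_a$transcripts$gene_id)
  res <- go_enrichment(sim$go$designated, bg, sim$go$gene2terms)
  expect_equal(res$term[1], sim$go$planted_term)
  expect_true(res$significant[1])
  # BH keeps q monotone in rank order and never below p
  expect_true(all(res$q >= res$p - 1e-12))
  expect_true(all(diff(res$q[order(res$p)]) >= -1e-12))
})
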