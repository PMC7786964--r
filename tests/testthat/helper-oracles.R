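# Brute-force oracles, independent of the package implementations.

# exonic overlap: explicit base-set intersection
oracle_overlap_bp <- function(a, b) {
  if (a$chrom[1] != b$chrom[1]) return(0L)
  ba <- unlist(mapply(seq, a$start, a$end, SIMPLIFY = FALSE))
  bb <- unlist(mapply(seq, b$start, b$end, SIMPLIFY = FALSE))
  length(intersect(ba, bb))
}

# class-code assignment by enumerating all novel x reference pairs
oracle_classify <- function(novel, reference) {
  out <- character(0)
  ref_ids <- reference$transcripts$transcript_id
  for (id in novel$transcripts$transcript_id) {
    ne <- novel$exons[novel$exons$transcript_id == id, ]
    if (ne$strand[1] == ".") next
    sense <- FALSE; anti <- FALSE; intronic <- FALSE
    for (rid in ref_ids) {
      re <- reference$exons[reference$exons$transcript_id == rid, ]
      ov <- oracle_overlap_bp(ne, re)
      if (ov > 0) {
        if (ne$strand[1] == re$strand[1]) sense <- TRUE else anti <- TRUE
      }
    }
    if (!sense && !anti) {
      span <- c(min(ne$start), max(ne$end))
      for (rid in ref_ids) {
        re <- reference$exons[reference$exons$transcript_id == rid, ]
        if (re$chrom[1] != ne$chrom[1] || nrow(re) < 2) next
        re <- re[order(re$start), ]
        for (j in seq_len(nrow(re) - 1)) {
          if (re$end[j] + 1 <= span[1] && span[2] <= re$start[j + 1] - 1)
            intronic <- TRUE
        }
      }
    }
    out[id] <- if (sense) "sense" else if (anti) "x"
               else if (intronic) "i" else "u"
  }
  out
}

# longest ORF by exhaustive scan over every (ATG, downstream stop) pair
oracle_orf <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  best <- 0L
  for (i in seq_len(max(0, n - 2))) {
    if (substr(seq, i, i + 2) != "ATG") next
    j <- i
    len <- 0L
    repeat {
      if (j + 2 > n) break
      cod <- substr(seq, j, j + 2)
      len <- len + 3L
      if (cod %in% c("TAA", "TAG", "TGA")) break
      j <- j + 3L
    }
    best <- max(best, len)
  }
  best
}

# exact two-sided rank-sum p by enumerating all group assignments
oracle_wilcoxon <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(m + n, m)
  u_all <- apply(combs, 2, function(idx)
    sum(r[idx]) - m * (m + 1) / 2)
  pl <- mean(u_all <= u_obs)
  pu <- mean(u_all >= u_obs)
  min(1, 2 * min(pl, pu))
}

# two-sided Fisher p by enumerating all tables with fixed margins
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  lo <- max(0, n1 - m2); hi <- min(n1, m1)
  probs <- vapply(lo:hi, function(k)
    stats::dhyper(k, m1, m2, n1), numeric(1))
  p_obs <- stats::dhyper(a, m1, m2, n1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# KS statistic by scanning the pooled support
oracle_ks_d <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t),
                 numeric(1))))
}

# Pearson r straight from the covariance formula
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# connected components by iterated transitive closure over an edge list
oracle_components <- function(edges) {
  nodes <- unique(c(edges[[1]], edges[[2]]))
  comp <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(edges))) {
      a <- edges[[1]][i]; b <- edges[[2]][i]
      if (comp[a] != comp[b]) {
        comp[comp == max(comp[a], comp[b])] <- min(comp[a], comp[b])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(names(comp), comp)
}

# hypergeometric upper tail from binomial coefficients
oracle_hyper_p <- function(k, K, n, N) {
  sum(vapply(k:min(K, n), function(j)
    choose(K, j) * choose(N - K, n - j), numeric(1))) / choose(N, n)
}
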