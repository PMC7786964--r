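# shared fixtures built in code

# quick exon-table builder: exons as list of c(start, end)
mk_tx <- function(id, exons, chrom = "c1", strand = "+",
                  gene = paste0("g_", id)) {
  data.frame(transcript_id = id, gene_id = gene, chrom = chrom,
             start = vapply(exons, `[`, numeric(1), 1),
             end = vapply(exons, `[`, numeric(1), 2),
             strand = strand, stringsAsFactors = FALSE)
}

mk_ann <- function(..., chrom_sizes = NULL) {
  annotation(do.call(rbind, list(...)), chrom_sizes = chrom_sizes)
}

# random toy annotation for property tests
random_annotation <- function(n_tx, chroms = c("c1", "c2"),
                              max_pos = 5000) {
  rows <- lapply(seq_len(n_tx), function(i) {
    n_ex <- sample(1:3, 1)
    s <- sort(sample(seq_len(max_pos - 200), n_ex))
    w <- sample(20:120, n_ex, replace = TRUE)
    e <- s + w
    # enforce non-overlap between consecutive exons
    for (j in seq_len(n_ex)[-1]) {
      if (s[j] <= e[j - 1]) s[j] <- e[j - 1] + sample(5:50, 1)
      e[j] <- s[j] + w[j]
    }
    mk_tx(sprintf("t%03d", i), mapply(c, s, e, SIMPLIFY = FALSE),
          chrom = sample(chroms, 1),
          strand = sample(c("+", "-"), 1))
  })
  annotation(do.call(rbind, rows))
}

# session-cached synthetic study (the generator is deterministic, so
# one instance serves every test file)
study_cache <- new.env(parent = emptyenv())
get_study <- function(seed = 7) {
  key <- paste0("s", seed)
  if (is.null(study_cache[[key]]))
    study_cache[[key]] <- simulate_study(sim_config(seed = seed))
  study_cache[[key]]
}

toy_genome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}
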