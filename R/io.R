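#' Read transcript models from a GTF file
#'
#' Exon features are grouped by `transcript_id` into transcript models;
#' 1-based inclusive coordinates are preserved as-is. Unstranded (".")
#' transcripts are accepted here and excluded later by the strand-aware
#' classifier.
#'
#' @param path GTF file. Lines must have 9 tab-separated fields; exon
#'   features must carry `transcript_id` and `gene_id` attributes.
#' @param chrom_sizes optional named vector of chromosome lengths used
#'   to validate coordinates.
#' @return an [annotation()] object. An empty file yields an empty
#'   annotation with a warning.
#' @export
read_gtf <- function(path, chrom_sizes = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  if (!any(keep)) {
    warning("GTF file ", path, " contains no feature lines")
    return(annotation(data.frame(transcript_id = character(),
                                 gene_id = character(), chrom = character(),
                                 start = integer(), end = integer(),
                                 strand = character())))
  }
  ntab <- lengths(gregexpr("\t", lines[keep], fixed = TRUE))
  ntab[!grepl("\t", lines[keep], fixed = TRUE)] <- 0L
  bad <- which(ntab != 8L)
  if (length(bad))
    parse_error(path, which(keep)[bad[1]],
                sprintf("expected 9 tab-separated columns, found %d",
                        ntab[bad[1]] + 1L))

  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  mat <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  lineno <- which(keep)
  attr_field <- mat[, 9L]
  get_attr <- function(key) {
    m <- regmatches(attr_field,
                    regexpr(sprintf('%s "[^"]*"', key), attr_field))
    out <- rep(NA_character_, length(attr_field))
    hit <- grepl(sprintf('%s "', key), attr_field, fixed = TRUE)
    out[hit] <- sub(sprintf('^%s "([^"]*)"$', key), "\\1", m)
    out
  }
  type <- mat[, 3L]
  tid <- get_attr("transcript_id")
  gid <- get_attr("gene_id")
  biotype <- get_attr("biotype")

  is_exon <- type == "exon"
  if (any(is_exon & (is.na(tid) | is.na(gid))))
    parse_error(path, lineno[which(is_exon & (is.na(tid) | is.na(gid)))[1]],
                "exon feature lacks transcript_id or gene_id attribute")
  start <- suppressWarnings(as.integer(mat[, 4L]))
  end <- suppressWarnings(as.integer(mat[, 5L]))
  badc <- which(is_exon & (is.na(start) | is.na(end)))
  if (length(badc))
    parse_error(path, lineno[badc[1]], "non-numeric exon coordinates")

  # transcripts declared by a transcript feature but owning no exon line
  declared <- unique(tid[type == "transcript" & !is.na(tid)])
  orphans <- setdiff(declared, tid[is_exon])
  if (length(orphans))
    stop("transcript with zero exons in ", path, ": ", orphans[1])

  ex <- data.frame(transcript_id = tid[is_exon], gene_id = gid[is_exon],
                   chrom = mat[is_exon, 1L], start = start[is_exon],
                   end = end[is_exon], strand = mat[is_exon, 7L],
                   biotype = biotype[is_exon], stringsAsFactors = FALSE)
  annotation(ex, chrom_sizes = chrom_sizes)
}

#' Write an annotation as GTF
#'
#' Emits one exon line per exon, sorted by chromosome then start, with
#' GTF2.2 attribute quoting. The transcript biotype (class label), when
#' present, is emitted as a `biotype` attribute.
#'
#' @param x an [annotation()] object.
#' @param path output file.
#' @param source value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(x, path, source = "lncscape") {
  ex <- x$exons
  ex <- ex[order(ex$chrom, ex$start, ex$transcript_id), , drop = FALSE]
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                   ex$gene_id, ex$transcript_id)
  has_bt <- !is.na(ex$biotype)
  attrs[has_bt] <- paste0(attrs[has_bt],
                          sprintf(' biotype "%s";', ex$biotype[has_bt]))
  lines <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                   ex$chrom, source, ex$start, ex$end, ex$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet] named by the first whitespace
#'   token of each header, with sequences uppercased. Duplicate headers
#'   are an error.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA header: ",
         names(seqs)[duplicated(names(seqs))][1])
  Biostrings::DNAStringSet(toupper(seqs))
}

#' Chromosome sizes of a genome
#' @param genome a `DNAStringSet` from [read_genome_fasta()].
#' @return named integer vector of sequence lengths.
#' @export
genome_sizes <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

# shared tabular reader: tab-separated, locale-independent numerics,
# "NA"/"" -> missing, column-count mismatches reported with line numbers
read_tsv_checked <- function(path, col_names, col_classes,
                             header = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  body <- lines[keep]
  lineno <- which(keep)
  if (header && length(body)) {
    body <- body[-1]
    lineno <- lineno[-1]
  }
  n <- length(col_names)
  if (!length(body)) {
    out <- as.data.frame(stats::setNames(
      lapply(col_classes, function(cl) vector(cl, 0L)), col_names),
      stringsAsFactors = FALSE)
    return(out)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != n)
  if (length(bad))
    parse_error(path, lineno[bad[1]],
                sprintf("expected %d columns, found %d", n,
                        lengths(parts)[bad[1]]))
  mat <- matrix(unlist(parts), ncol = n, byrow = TRUE)
  out <- lapply(seq_len(n), function(j) {
    v <- mat[, j]
    v[v %in% c("NA", "")] <- NA
    switch(col_classes[j],
           character = v,
           integer = as.integer(v),
           numeric = as.numeric(v),
           logical = {
             num <- suppressWarnings(as.numeric(v))
             ifelse(is.na(num), v %in% c("TRUE", "true"), num != 0)
           })
  })
  names(out) <- col_names
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Read a transposable-element track (BED3 + class label)
#'
#' Input coordinates are BED-style 0-based half-open; they are converted
#' to the package's internal 1-based inclusive convention on the way in.
#'
#' @param path tab-separated file `chrom start end te_class`.
#' @return data.frame `chrom`, `start`, `end` (1-based inclusive),
#'   `te_class`.
#' @export
read_te_track <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "start", "end", "te_class"),
                         c("character", "integer", "integer", "character"))
  if (any(df$start >= df$end))
    stop("TE record with start >= end (BED half-open expected)")
  df$start <- df$start + 1L
  df
}

#' Read a feature-by-sample count table
#'
#' @param path tab-separated file with a header line `feature_id` +
#'   sample names, one row per feature.
#' @return numeric matrix (features x samples). Negative entries are an
#'   error.
#' @export
read_counts_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  if (anyNA(m)) stop("non-numeric entry in count table ", path)
  if (any(m < 0)) stop("negative entry in count table ", path)
  m
}

#' Assemble an expression table
#'
#' Bundles raw counts with the metadata needed for RPKM: exon-model
#' lengths, sample-to-group assignment and per-sample library sizes
#' (total mapped reads).
#'
#' @param counts numeric matrix, features x samples, non-negative.
#' @param feature_lengths named vector of exon-model lengths (bp) for
#'   at least every row of `counts`.
#' @param sample_groups named character vector mapping every column of
#'   `counts` to a group.
#' @param library_sizes named vector of total mapped reads per sample;
#'   defaults to the column sums of `counts`.
#' @return an object of class `lnc_expression`.
#' @export
expression_table <- function(counts, feature_lengths, sample_groups,
                             library_sizes = colSums(counts)) {
  if (any(counts < 0)) stop("negative count")
  miss <- setdiff(colnames(counts), names(sample_groups))
  if (length(miss)) stop("samples without group: ", paste(miss, collapse = ", "))
  missL <- setdiff(rownames(counts), names(feature_lengths))
  if (length(missL))
    stop("features without length: ", paste(utils::head(missL, 3), collapse = ", "))
  if (any(feature_lengths[rownames(counts)] <= 0))
    stop("non-positive feature length")
  if (is.null(names(library_sizes))) names(library_sizes) <- colnames(counts)
  if (any(library_sizes[colnames(counts)] <= 0))
    stop("non-positive library size")
  structure(list(counts = counts,
                 feature_lengths = feature_lengths[rownames(counts)],
                 sample_groups = sample_groups[colnames(counts)],
                 library_sizes = library_sizes[colnames(counts)]),
            class = "lnc_expression")
}

#' @export
print.lnc_expression <- function(x, ...) {
  cat(sprintf("<lnc_expression> %d features x %d samples in %d groups\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$sample_groups))))
  invisible(x)
}

#' Read a coding-evidence table
#'
#' One row per transcript with boolean verdicts from external coding
#' predictors (CPC, CNCI) and homology searches (BLASTX vs SwissProt,
#' HMMER vs Pfam, both at E <= 1e-3). Transcripts absent from the table
#' are treated downstream as having no evidence of coding.
#'
#' @param path tab-separated file with header `transcript_id cpc_coding
#'   cnci_coding blastx_hit pfam_hit` (0/1 or TRUE/FALSE).
#' @return data.frame with logical evidence columns.
#' @export
read_evidence_table <- function(path) {
  read_tsv_checked(path,
                   c("transcript_id", "cpc_coding", "cnci_coding",
                     "blastx_hit", "pfam_hit"),
                   c("character", rep("logical", 4)), header = TRUE)
}

# evidence lookup with the missing-transcript-means-no-evidence default
evidence_flags <- function(evidence, ids) {
  out <- data.frame(transcript_id = ids,
                    cpc_coding = FALSE, cnci_coding = FALSE,
                    blastx_hit = FALSE, pfam_hit = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(evidence) && nrow(evidence)) {
    m <- match(ids, evidence$transcript_id)
    hit <- !is.na(m)
    for (col in c("cpc_coding", "cnci_coding", "blastx_hit", "pfam_hit"))
      out[[col]][hit] <- isTRUE_vec(evidence[[col]][m[hit]])
  }
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Read BLAST tabular output (outfmt 6)
#'
#' @param path 12-column BLAST tabular file.
#' @return data.frame with the standard outfmt-6 columns (`qseqid`,
#'   `sseqid`, `pident`, `length`, `mismatch`, `gapopen`, `qstart`,
#'   `qend`, `sstart`, `send`, `evalue`, `bitscore`).
#' @export
read_blast_tabular <- function(path) {
  df <- read_tsv_checked(path,
                         c("qseqid", "sseqid", "pident", "length", "mismatch",
                           "gapopen", "qstart", "qend", "sstart", "send",
                           "evalue", "bitscore"),
                         c("character", "character", rep("numeric", 10)))
  if (any(df$evalue < 0, na.rm = TRUE)) stop("negative E-value")
  df
}

#' Read an ortholog pair table
#'
#' @param path tab-separated `gene_a gene_b group_id` (OrthoMCL-style
#'   1:1 pairs between two species). A gene assigned to more than one
#'   group is an error.
#' @return data.frame `gene_a`, `gene_b`, `group_id`.
#' @export
read_ortholog_table <- function(path) {
  df <- read_tsv_checked(path, c("gene_a", "gene_b", "group_id"),
                         rep("character", 3))
  for (col in c("gene_a", "gene_b")) {
    tab <- unique(df[, c(col, "group_id")])
    if (anyDuplicated(tab[[col]]))
      stop("gene in more than one ortholog group: ",
           tab[[col]][duplicated(tab[[col]])][1])
  }
  df
}

#' Read a differential-expression result table
#'
#' @param path tab-separated file with header `feature_id log2fc pvalue
#'   padj`; `"NA"` or empty fields become missing values.
#' @return data.frame `feature_id`, `log2fc`, `pvalue`, `padj`.
#' @export
read_de_table <- function(path) {
  read_tsv_checked(path, c("feature_id", "log2fc", "pvalue", "padj"),
                   c("character", rep("numeric", 3)), header = TRUE)
}

#' Read GO annotations
#'
#' @param path tab-separated `gene<TAB>term;term;...`.
#' @param term_path optional tab-separated `term_id name namespace`
#'   table; terms referenced by genes but absent here are reported as
#'   orphans via a warning.
#' @return list with `gene2terms` (named list of character vectors) and
#'   `terms` (data.frame or NULL).
#' @export
read_go_annotations <- function(path, term_path = NULL) {
  df <- read_tsv_checked(path, c("gene", "terms"),
                         c("character", "character"))
  gene2terms <- stats::setNames(strsplit(df$terms, ";", fixed = TRUE),
                                df$gene)
  terms <- NULL
  if (!is.null(term_path)) {
    terms <- read_tsv_checked(term_path, c("term_id", "name", "namespace"),
                              rep("character", 3))
    orphan <- setdiff(unique(unlist(gene2terms)), terms$term_id)
    if (length(orphan))
      warning("GO terms without a name entry: ",
              paste(utils::head(orphan, 5), collapse = ", "))
  }
  list(gene2terms = gene2terms, terms = terms)
}

# deterministic TSV writer used by the pipeline stages
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
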