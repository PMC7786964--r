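#' Call differentially expressed (sex-biased) features
#'
#' A feature is up-regulated iff `log2fc >= min_abs_log2fc` and
#' `padj < max_padj`; down-regulated iff `log2fc <= -min_abs_log2fc`
#' and `padj < max_padj`. Rows with a missing adjusted p-value are
#' excluded. With the default orientation, "up" means higher in the
#' first (e.g. male/testis) level of the comparison; `strict = TRUE`
#' switches the fold-change rule to a strict inequality.
#'
#' @param de data.frame from [read_de_table()].
#' @param min_abs_log2fc fold-change threshold (inclusive by default).
#' @param max_padj adjusted-p threshold (exclusive).
#' @param strict use `|log2fc| >` instead of `>=`.
#' @return list `up` and `down`, character vectors of feature ids.
#' @export
call_biased <- function(de, min_abs_log2fc = 1.0, max_padj = 0.05,
                        strict = FALSE) {
  stopifnot(min_abs_log2fc > 0, max_padj > 0)
  ok <- !is.na(de$padj) & de$padj < max_padj
  fc_up <- if (strict) de$log2fc > min_abs_log2fc
           else de$log2fc >= min_abs_log2fc
  fc_dn <- if (strict) de$log2fc < -min_abs_log2fc
           else de$log2fc <= -min_abs_log2fc
  list(up = de$feature_id[ok & !is.na(de$log2fc) & fc_up],
       down = de$feature_id[ok & !is.na(de$log2fc) & fc_dn])
}

#' Test lncRNA male-bias enrichment against PCGs
#'
#' Two-sided Fisher's exact test on the 2x2 table of male- vs
#' female-biased feature counts for PCGs and lncRNAs.
#'
#' @param pcg_male,pcg_female,lnc_male,lnc_female non-negative counts.
#' @return an `lnc_test` whose statistic is the sample odds ratio
#'   `(pcg_male * lnc_female) / (pcg_female * lnc_male)`.
#' @export
sex_bias_fisher <- function(pcg_male, pcg_female, lnc_male, lnc_female) {
  fisher_exact_2x2(matrix(c(pcg_male, pcg_female, lnc_male, lnc_female),
                          2, dimnames = list(c("male", "female"),
                                             c("pcg", "lnc"))))
}
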