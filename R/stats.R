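#' Statistical kernels
#'
#' Thin, contract-explicit wrappers around the standard tests used
#' throughout the reports. Each returns an `lnc_test` object with
#' elements `statistic`, `p_value`, `method` and `alternative`
#' (always two-sided).
#'
#' @name stat_tests
NULL

lnc_test <- function(statistic, p_value, method) {
  structure(list(statistic = unname(statistic),
                 p_value = unname(p_value),
                 method = method, alternative = "two.sided"),
            class = "lnc_test")
}

#' @export
print.lnc_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g (two-sided)\n",
              x$method, x$statistic, x$p_value))
  invisible(x)
}

#' Two-tailed Wilcoxon rank-sum test
#'
#' Exact p by enumeration when the combined sample size is at most 20
#' and there are no ties; otherwise the tie-corrected normal
#' approximation without continuity correction.
#'
#' @param x,y non-empty numeric vectors.
#' @return an `lnc_test` with the rank-sum statistic W.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty input")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y)) <= 20 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = FALSE))
  lnc_test(res$statistic, res$p.value,
           if (use_exact) "Wilcoxon rank sum (exact)"
           else "Wilcoxon rank sum (normal approximation)")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_x - ECDF_y|` with the asymptotic two-sided p-value.
#'
#' @param x,y non-empty numeric vectors.
#' @return an `lnc_test`.
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty input")
  res <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  lnc_test(res$statistic, res$p.value, "Two-sample Kolmogorov-Smirnov")
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p as the sum of hypergeometric probabilities no larger
#' than the observed table's, margins fixed. The odds ratio is the
#' sample ratio `ad/bc` (0 and Inf allowed), not the conditional MLE.
#' A table with a zero margin carries no information: p = 1.
#'
#' @param tab 2x2 matrix of non-negative integers.
#' @return an `lnc_test` with the odds ratio as statistic.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(lnc_test(or, 1, "Fisher's exact test"))
  res <- stats::fisher.test(tab)
  lnc_test(or, res$p.value, "Fisher's exact test")
}

#' Chi-squared test of independence on an R x C table
#'
#' `sum (O - E)^2 / E` with expectations from the margins and
#' `df = (R-1)(C-1)`.
#'
#' @param tab matrix of non-negative counts; a zero row or column is an
#'   error.
#' @return an `lnc_test`; the degrees of freedom are attached as `df`.
#' @export
chi_squared_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  out <- lnc_test(res$statistic, res$p.value, "Chi-squared test")
  out$df <- unname(res$parameter)
  out
}

#' Pearson correlation with t-distribution p-value
#'
#' @param x,y numeric vectors of equal length >= 3, each with positive
#'   variance.
#' @return list `r`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  res <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(res$estimate), p_value = res$p.value, n = length(x))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return q-values (`p.adjust(..., "BH")`).
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}
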