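#' Reads per kilobase of exon model per million mapped reads
#'
#' `RPKM = 1e9 * C / (N * L)` with read count `C`, library size `N`
#' (total mapped reads) and exon-model length `L` in bp.
#'
#' @param count read count (vectorized).
#' @param library_size total mapped reads, > 0.
#' @param exon_length exon-model length in bp, > 0.
#' @return numeric RPKM values.
#' @export
rpkm <- function(count, library_size, exon_length) {
  if (any(library_size <= 0)) stop("library size must be positive")
  if (any(exon_length <= 0)) stop("exon length must be positive")
  if (any(count < 0)) stop("negative count")
  1e9 * count / (library_size * exon_length)
}

#' Per-sample RPKM matrix of an expression table
#'
#' @param expr an [expression_table()].
#' @return numeric matrix, features x samples.
#' @export
rpkm_matrix <- function(expr) {
  stopifnot(inherits(expr, "lnc_expression"))
  sweep(expr$counts / expr$feature_lengths, 2, expr$library_sizes, "/") * 1e9
}

#' Replicate-averaged expression profile
#'
#' Converts counts to per-sample RPKM and takes the arithmetic mean of
#' replicates within each group.
#'
#' @param expr an [expression_table()].
#' @param groups optional subset / ordering of groups to keep; defaults
#'   to all groups in first-appearance order.
#' @return numeric matrix, features x groups, of mean RPKM.
#' @export
average_replicates <- function(expr, groups = NULL) {
  m <- rpkm_matrix(expr)
  gs <- expr$sample_groups
  if (is.null(groups)) groups <- unique(gs)
  absent <- setdiff(groups, gs)
  if (length(absent))
    stop("group with zero samples: ", paste(absent, collapse = ", "))
  out <- vapply(groups, function(g)
    rowMeans(m[, gs == g, drop = FALSE]), numeric(nrow(m)))
  if (nrow(m) == 1L) out <- matrix(out, nrow = 1,
                                   dimnames = list(rownames(m), groups))
  out
}

# base-2 Shannon entropy of a probability vector (0 log 0 = 0)
entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Jensen-Shannon tissue-specificity score of one profile
#'
#' The profile is normalized to a probability vector `p`; for each
#' group `t` with one-hot indicator `d_t`, the Jensen-Shannon
#' divergence `JSD(p, d_t) = H((p + d_t)/2) - (H(p) + H(d_t))/2` is
#' computed with base-2 entropy `H`, and the score is
#' `max_t (1 - sqrt(JSD(p, d_t)))`. 1 means expression confined to a
#' single group; uniform profiles give the minimal score.
#'
#' @param x non-negative expression vector over groups (linear scale).
#' @return list `score` (NA for an all-zero profile) and `which_max`
#'   (index of the maximizing group).
#' @export
js_specificity <- function(x) {
  if (any(x < 0)) stop("negative expression value")
  s <- sum(x)
  if (s == 0) return(list(score = NA_real_, which_max = NA_integer_))
  p <- x / s
  hp <- entropy2(p)
  scores <- vapply(seq_along(p), function(t) {
    m <- p / 2
    m[t] <- m[t] + 0.5
    jsd <- entropy2(m) - hp / 2
    1 - sqrt(max(jsd, 0))
  }, numeric(1))
  list(score = max(scores), which_max = which.max(scores))
}

#' Tau tissue-specificity index of one profile
#'
#' `tau = sum_i (1 - x_i / max_j x_j) / (n - 1)`: 0 for a uniform
#' profile, 1 when a single group carries all expression.
#'
#' @param x non-negative expression vector over `n >= 2` groups.
#' @return tau in `[0, 1]`, or NA for an all-zero profile.
#' @export
tau_index <- function(x) {
  if (any(x < 0)) stop("negative expression value")
  if (length(x) < 2L) stop("tau needs at least two groups")
  mx <- max(x)
  if (mx == 0) return(NA_real_)
  sum(1 - x / mx) / (length(x) - 1)
}

#' Expression tier from the maximum RPKM
#'
#' @param rpkm_max per-feature maximum RPKM over samples (or groups).
#' @param breaks tier boundaries: below the first is `low`, at or above
#'   the second is `high`.
#' @return factor with levels `low`, `moderate`, `high`.
#' @export
assign_tiers <- function(rpkm_max, breaks = c(5, 50)) {
  cut(rpkm_max, breaks = c(-Inf, breaks, Inf),
      labels = c("low", "moderate", "high"), right = FALSE)
}

#' Specificity scores for every feature of a profile matrix
#'
#' @param profile features x groups matrix of mean RPKM (see
#'   [average_replicates()]).
#' @param tier_from optional per-feature RPKM_max vector for tier
#'   assignment; defaults to the row maxima of `profile`.
#' @return data.frame `feature_id`, `js_score`, `tau`, `tissue_of_max`,
#'   `rpkm_max`, `tier`; all-zero features carry NA scores.
#' @export
specificity_scores <- function(profile, tier_from = NULL) {
  if (ncol(profile) < 2L) stop("specificity scoring needs >= 2 groups")
  js <- apply(profile, 1, js_specificity)
  score <- vapply(js, `[[`, numeric(1), "score")
  wmax <- vapply(js, `[[`, numeric(1), "which_max")
  rmax <- apply(profile, 1, max)
  data.frame(
    feature_id = rownames(profile) %||% as.character(seq_len(nrow(profile))),
    js_score = score,
    tau = apply(profile, 1, tau_index),
    tissue_of_max = ifelse(is.na(wmax), NA_character_,
                           colnames(profile)[wmax]),
    rpkm_max = rmax,
    tier = assign_tiers(tier_from %||% rmax),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare two specificity-score distributions
#'
#' Two-sample two-sided Kolmogorov-Smirnov test, dropping missing
#' scores.
#'
#' @param scores_a,scores_b numeric score vectors.
#' @return an `lnc_test` result (see [ks_two_sample()]).
#' @export
compare_specificity <- function(scores_a, scores_b) {
  ks_two_sample(scores_a[!is.na(scores_a)], scores_b[!is.na(scores_b)])
}

#' Call highly tissue-specific features
#'
#' @param scores data.frame from [specificity_scores()].
#' @param js_threshold minimum JS score (inclusive).
#' @return list with `features` (the qualifying rows), `by_tissue`
#'   (table of `tissue_of_max`) and `by_tier` (tier breakdown).
#' @export
call_highly_specific <- function(scores, js_threshold = 0.95) {
  hit <- !is.na(scores$js_score) & scores$js_score >= js_threshold
  f <- scores[hit, , drop = FALSE]
  list(features = f,
       by_tissue = table(f$tissue_of_max),
       by_tier = table(f$tier))
}
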