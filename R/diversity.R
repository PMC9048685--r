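# Alpha diversity: per-sample peptide richness and Shannon index, with
# nonparametric comparisons between clinical groups.

#' Per-sample peptide richness
#'
#' Richness of a sample is the number of peptides with nonzero abundance.
#'
#' @param x nonnegative numeric vector (one sample) or intensity matrix
#'   (samples in rows).
#' @return integer count, or named integer vector for a matrix.
#' @export
richness <- function(x) {
  if (is.matrix(x)) {
    validate_intensity_matrix(x)
    return(apply(x, 1L, function(r) sum(r > 0)))
  }
  if (any(x < 0)) abort_fmt("abundances must be nonnegative")
  sum(x > 0)
}

#' Shannon diversity of a sample (nats)
#'
#' `H = -sum_i p_i ln p_i` with `p_i` the within-sample relative abundance of
#' peptide i; terms with zero abundance contribute 0 by convention, so
#' samples with different peptide counts are comparable. Note the index is
#' returned with the standard sign (nonnegative); `H = 0` for samples with
#' at most one detected peptide.
#'
#' @param x nonnegative numeric vector or intensity matrix (samples in rows).
#' @return Shannon index in nats (vector for a matrix input).
#' @export
shannon <- function(x) {
  if (is.matrix(x)) {
    validate_intensity_matrix(x)
    return(apply(x, 1L, shannon))
  }
  if (any(x < 0)) abort_fmt("abundances must be nonnegative")
  tot <- sum(x)
  if (tot == 0) return(0)
  p <- x[x > 0] / tot
  -sum(p * log(p))
}

#' Compare alpha diversity between clinical groups
#'
#' Two groups are compared with the two-sided Wilcoxon rank-sum test; three
#' or more with the Kruskal-Wallis test. `stats::wilcox.test` computes the
#' exact null distribution below 50 observations per group when there are no
#' ties, and the tie-corrected normal approximation otherwise, so reported
#' p-values are reproducible.
#'
#' @param values per-sample diversity values (richness or Shannon).
#' @param groups factor (or coercible) of group membership, same length.
#' @return list with `test`, `statistic`, `p_value` and per-group `n`.
#' @export
compare_alpha_diversity <- function(values, groups) {
  groups <- as.factor(droplevels(as.factor(groups)))
  stopifnot(length(values) == length(groups))
  n <- table(groups)
  if (nlevels(groups) < 2L) abort_fmt("need at least 2 groups")
  if (any(n < 1L)) abort_fmt("every group needs at least one observation")
  if (nlevels(groups) == 2L) {
    ht <- suppressWarnings(
      stats::wilcox.test(values[groups == levels(groups)[1L]],
                         values[groups == levels(groups)[2L]],
                         alternative = "two.sided"))
    if (is.nan(ht$p.value)) ht$p.value <- 1   # fully tied data: no evidence
    test <- "wilcoxon_rank_sum"
  } else {
    ht <- stats::kruskal.test(values, groups)
    test <- "kruskal_wallis"
  }
  list(test = test, statistic = unname(ht$statistic),
       p_value = unname(ht$p.value), n = as.integer(n),
       groups = levels(groups))
}

#' Diversity profile of a cohort
#'
#' Convenience wrapper: per-sample richness and Shannon index plus a group
#' comparison for one clinical variable.
#'
#' @param m intensity matrix.
#' @param clinical validated clinical table aligned with `m` rows.
#' @param by clinical variable to compare by (`"stage"`, `"grade"`, `"tils"`
#'   use the dichotomization rules of [comparison_spec()]; `"gender"` and
#'   `"site"` their two categories; `"age"` is compared across tertiles).
#' @return list: `per_sample` data frame, `richness_test`, `shannon_test`.
#' @export
diversity_profile <- function(m, clinical,
                              by = c("stage", "grade", "tils", "gender",
                                     "site", "age")) {
  by <- match.arg(by)
  validate_intensity_matrix(m)
  validate_clinical_table(clinical)
  idx <- match(rownames(m), clinical$sample_id)
  if (anyNA(idx)) abort_fmt("sample '%s' missing from the clinical table",
                            rownames(m)[which(is.na(idx))[1L]])
  clin <- clinical[idx, ]
  groups <- switch(by,
    stage = , grade = , tils = assign_groups(clin, comparison_spec(by)),
    gender = factor(clin$gender),
    site = factor(clin$site),
    age = cut(clin$age, stats::quantile(clin$age, c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE,
              labels = c("age_low", "age_mid", "age_high")))
  rich <- richness(m)
  h <- shannon(m)
  list(per_sample = data.frame(sample_id = rownames(m), richness = rich,
                               shannon = h, group = as.character(groups),
                               stringsAsFactors = FALSE, row.names = NULL),
       richness_test = compare_alpha_diversity(rich, groups),
       shannon_test = compare_alpha_diversity(h, groups))
}
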