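# Principal component partial R-squared (PCPR2): proportion of total
# metaproteome variability attributable to each clinical variable, computed
# as eigenvalue-weighted R-squared of per-component regressions.

#' Principal component analysis of a (log) intensity matrix
#'
#' Columns are mean-centered; scores and eigenvalues come from the singular
#' value decomposition, so eigenvalues are the variances of the component
#' scores (divisor n - 1) in nonincreasing order.
#'
#' @param m numeric matrix, samples in rows (log-transform upstream).
#' @param n_components number of components to retain; default all nonzero,
#'   at most `min(n_samples - 1, n_features)`.
#' @return list with `scores` (samples x k), `eigenvalues` (length k),
#'   `rotation`, `center`, `total_variance`.
#' @export
run_pca <- function(m, n_components = NULL) {
  if (!is.matrix(m) || !is.numeric(m)) abort_fmt("`m` must be a numeric matrix")
  n <- nrow(m)
  if (n < 2L) abort_fmt("need at least 2 samples for PCA")
  kmax <- min(n - 1L, ncol(m))
  if (is.null(n_components)) n_components <- kmax
  if (n_components < 1L || n_components > kmax) {
    abort_fmt("n_components must lie in [1, %d]", kmax)
  }
  ctr <- colMeans(m)
  xc <- sweep(m, 2L, ctr)
  sv <- svd(xc, nu = n_components, nv = n_components)
  ev <- (sv$d^2) / (n - 1L)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  rownames(scores) <- rownames(m)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  list(scores = scores, eigenvalues = ev[seq_len(n_components)],
       rotation = sv$v, center = ctr,
       total_variance = sum(xc^2) / (n - 1L))
}

# R-squared of the regression of a score vector on one clinical variable:
# categorical variables enter as group indicators (one-way ANOVA R2),
# continuous ones as a single regressor.
score_r2 <- function(score, v) {
  if (is.character(v) || is.factor(v) || is.logical(v)) v <- factor(v)
  fit <- stats::lm(score ~ v)
  summary(fit)$r.squared
}

#' PCPR2 explained-variance decomposition
#'
#' Two steps: (1) for each clinical variable and each retained principal
#' component, the R-squared of the regression of the component scores on the
#' variable (one-way ANOVA R-squared for categorical variables); (2) per
#' variable, the explained proportion of whole-dataset variability is the
#' sum of those R-squared values weighted by the normalized PCA eigenvalues.
#' Each variable is assessed marginally.
#'
#' @param m numeric matrix (log intensities), samples in rows.
#' @param clinical validated clinical table covering the samples of `m`.
#' @param variables clinical variables to assess (columns of `clinical`);
#'   `gender`, `site`, `stage`, `grade` are treated as categorical, `age`
#'   and `tils` as continuous.
#' @param n_components components to retain (default: all nonzero).
#' @return a `pcpr2_result`: list with `explained` (named proportions in
#'   `[0, 1]`), `r2` (variables x components), `eigenvalues`, `weights`.
#' @export
compute_pcpr2 <- function(m, clinical,
                          variables = c("gender", "age", "site", "stage",
                                        "grade", "tils"),
                          n_components = NULL) {
  validate_clinical_table(clinical)
  idx <- match(rownames(m), clinical$sample_id)
  if (anyNA(idx)) abort_fmt("sample '%s' missing from the clinical table",
                            rownames(m)[which(is.na(idx))[1L]])
  clin <- clinical[idx, ]
  missing <- setdiff(variables, names(clin))
  if (length(missing)) abort_fmt("unknown clinical variable '%s'", missing[1L])
  categorical <- c("gender", "site", "stage", "grade")

  pca <- run_pca(m, n_components)
  k <- length(pca$eigenvalues)
  keep <- pca$eigenvalues > 1e-12 * max(pca$eigenvalues)
  w <- pca$eigenvalues * keep
  w <- w / sum(w)

  r2 <- matrix(0, length(variables), k,
               dimnames = list(variables, colnames(pca$scores)))
  explained <- stats::setNames(numeric(length(variables)), variables)
  for (v in variables) {
    col <- clin[[v]]
    if (v %in% categorical) col <- factor(col)
    if (length(unique(col)) < 2L) {
      warning(sprintf("variable '%s' is constant across samples; explained = 0", v))
      next
    }
    for (j in seq_len(k)) {
      if (keep[j]) r2[v, j] <- score_r2(pca$scores[, j], col)
    }
    explained[v] <- sum(w * r2[v, ])
  }
  structure(list(explained = explained, r2 = r2,
                 eigenvalues = pca$eigenvalues, weights = w,
                 n_components = k),
            class = "pcpr2_result")
}

#' @export
print.pcpr2_result <- function(x, ...) {
  cat(sprintf("PCPR2 over %d components\n", x$n_components))
  print(round(100 * x$explained, 2))
  invisible(x)
}

#' Permutation reference for a PCPR2 explained proportion
#'
#' Re-computes the explained proportion of one variable after shuffling its
#' values across samples, giving a null distribution against which the
#' observed proportion can be ranked.
#'
#' @param m numeric matrix, samples in rows.
#' @param clinical clinical table.
#' @param variable single variable name.
#' @param n_permutations number of label shuffles.
#' @param n_components passed to [compute_pcpr2()].
#' @param seed integer seed.
#' @return list with `observed`, `null` (vector), `p_value`
#'   (`(1 + #{null >= observed}) / (B + 1)`).
#' @export
pcpr2_permutation_test <- function(m, clinical, variable,
                                   n_permutations = 200,
                                   n_components = NULL, seed = 1) {
  obs <- compute_pcpr2(m, clinical, variables = variable,
                       n_components = n_components)$explained[[1L]]
  null <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      clin_b <- clinical
      clin_b[[variable]] <- sample(clin_b[[variable]])
      compute_pcpr2(m, clin_b, variables = variable,
                    n_components = n_components)$explained[[1L]]
    }, numeric(1))
  })
  list(observed = obs, null = null,
       p_value = (1 + sum(null >= obs)) / (n_permutations + 1))
}
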