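# Ridge-regularized canonical correlation between two peptide blocks
# (typically an enriched microbial peptide cluster vs. the host peptide
# matrix), plus extraction of positively/negatively correlated feature
# clusters that feed back into the enrichment machinery.

# symmetric inverse square root via eigendecomposition
inv_sqrt_sym <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 1e-12)
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}

#' Ridge-regularized canonical correlation analysis
#'
#' Canonical directions solve the regularized CCA eigenproblem
#' `(Cxx + lambda1 I)^-1 Cxy (Cyy + lambda2 I)^-1 Cyx a = rho^2 a`,
#' computed via the symmetric form
#' `(Cxx + l1)^-1/2 Cxy (Cyy + l2)^-1 Cyx (Cxx + l1)^-1/2` so correlations
#' are real and clipped to `[0, 1]`. Regularization makes the problem
#' well-posed when features outnumber samples. Signs are fixed so the
#' largest-|loading| X feature of each variate is positive.
#'
#' @param X,Y numeric matrices with the same samples in rows (>= 3).
#' @param lambda1,lambda2 nonnegative ridge penalties for the two blocks.
#' @param ncomp number of canonical variates to return.
#' @return a `cca_result`: `cor` (nonincreasing canonical correlations),
#'   `xloadings`, `yloadings`, `xvariates`, `yvariates`, `lambda`.
#' @export
regularized_cca <- function(X, Y, lambda1 = 0, lambda2 = 0,
                            ncomp = 1) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.matrix(Y)) Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) abort_fmt("X and Y must share their samples")
  if (n < 3L) abort_fmt("need at least 3 samples for CCA")
  if (lambda1 < 0 || lambda2 < 0) abort_fmt("ridge penalties must be >= 0")
  ncomp <- min(ncomp, ncol(X), ncol(Y))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Cxx <- crossprod(Xc) / (n - 1) + diag(lambda1, ncol(X))
  Cyy <- crossprod(Yc) / (n - 1) + diag(lambda2, ncol(Y))
  Cxy <- crossprod(Xc, Yc) / (n - 1)
  Wx <- inv_sqrt_sym(Cxx)
  Wy <- inv_sqrt_sym(Cyy)
  K <- Wx %*% Cxy %*% Wy
  sv <- svd(K, nu = ncomp, nv = ncomp)
  rho <- pmin(pmax(sv$d[seq_len(ncomp)], 0), 1)
  a <- Wx %*% sv$u
  b <- Wy %*% sv$v
  # sign convention: largest-|loading| X feature positive per variate
  for (k in seq_len(ncomp)) {
    s <- sign(a[which.max(abs(a[, k])), k])
    if (s < 0) { a[, k] <- -a[, k]; b[, k] <- -b[, k] }
  }
  rownames(a) <- colnames(X)
  rownames(b) <- colnames(Y)
  structure(list(cor = rho, xloadings = a, yloadings = b,
                 xvariates = Xc %*% a, yvariates = Yc %*% b,
                 lambda = c(lambda1, lambda2), ncomp = ncomp),
            class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("regularized CCA (%d x %d features, lambda = %g / %g)\n",
              nrow(x$xloadings), nrow(x$yloadings),
              x$lambda[1L], x$lambda[2L]))
  cat("canonical correlations:", paste(round(x$cor, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Choose ridge penalties by leave-one-out first canonical correlation
#'
#' For every (lambda1, lambda2) pair on the grid, the model is refitted n
#' times leaving one sample out; held-out samples are projected on the
#' training variates and the grid point maximizing the correlation of the
#' held-out variate pairs is returned.
#'
#' @param X,Y data blocks.
#' @param grid numeric vector of candidate penalties (crossed for the two
#'   blocks).
#' @return list with `lambda1`, `lambda2`, `loo_cor` matrix.
#' @export
tune_rcca <- function(X, Y, grid = c(1e-3, 1e-2, 1e-1, 1)) {
  n <- nrow(X)
  loo <- matrix(NA_real_, length(grid), length(grid),
                dimnames = list(grid, grid))
  for (i in seq_along(grid)) {
    for (j in seq_along(grid)) {
      u <- v <- numeric(n)
      for (s in seq_len(n)) {
        fit <- regularized_cca(X[-s, , drop = FALSE], Y[-s, , drop = FALSE],
                               grid[i], grid[j], ncomp = 1)
        u[s] <- (X[s, ] - colMeans(X[-s, , drop = FALSE])) %*% fit$xloadings[, 1L]
        v[s] <- (Y[s, ] - colMeans(Y[-s, , drop = FALSE])) %*% fit$yloadings[, 1L]
      }
      loo[i, j] <- stats::cor(u, v)
    }
  }
  best <- which(loo == max(loo, na.rm = TRUE), arr.ind = TRUE)[1L, ]
  list(lambda1 = grid[best[[1L]]], lambda2 = grid[best[[2L]]], loo_cor = loo)
}

#' Correlated feature clusters from a CCA fit
#'
#' Features of the chosen block whose first-variate loading exceeds the
#' threshold in absolute value, split by loading sign into positively and
#' negatively correlated clusters.
#'
#' @param cca a `cca_result`.
#' @param block `"y"` (default: the searched block) or `"x"`.
#' @param threshold minimum |loading| on variate 1.
#' @return list with `positive` and `negative` feature id vectors.
#' @export
cca_clusters <- function(cca, block = c("y", "x"), threshold = 0.2) {
  block <- match.arg(block)
  stopifnot(inherits(cca, "cca_result"))
  ld <- if (block == "y") cca$yloadings[, 1L] else cca$xloadings[, 1L]
  # threshold on loadings normalized to the block maximum so the rule is
  # invariant to the overall scaling of the canonical direction
  ldn <- ld / max(abs(ld))
  list(positive = names(ldn)[ldn >= threshold],
       negative = names(ldn)[ldn <= -threshold])
}

#' Enrichment of CCA-correlated clusters
#'
#' Splits the chosen block's features into positively and negatively
#' correlated clusters at the loading threshold and runs empirical
#' enrichment for each nonempty cluster. Empty clusters are reported empty.
#'
#' @param cca a `cca_result`.
#' @param ann annotation table.
#' @param background background feature ids for the enrichment.
#' @param block,threshold passed to [cca_clusters()].
#' @param levels annotation levels to test.
#' @param B,seed permutation settings for [empirical_enrichment()].
#' @return list with `clusters` and per-cluster enrichment tables
#'   (`positive`, `negative`; `NULL` when the cluster is empty).
#' @export
correlated_cluster_enrichment <- function(cca, ann, background,
                                          block = c("y", "x"),
                                          threshold = 0.2,
                                          levels = ENRICHMENT_LEVELS,
                                          B = 1000, seed = 1) {
  block <- match.arg(block)
  cl <- cca_clusters(cca, block, threshold)
  seeds <- split_seed(seed, 2L)
  run <- function(feats, s) {
    if (!length(feats)) return(NULL)
    empirical_enrichment(feats, ann, background, levels, B = B, seed = s)
  }
  list(clusters = cl,
       positive = run(cl$positive, seeds[1L]),
       negative = run(cl$negative, seeds[2L]))
}
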