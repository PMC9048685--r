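# Sparse partial least squares discriminant analysis (sPLS-DA) with
# repeated-split stability selection, classification metrics and
# hierarchical clustering of samples on the selected peptide panel.
#
# The sparse PLS step follows the usual NIPALS-with-soft-thresholding
# scheme: per component, the X-weight vector is the leading left singular
# vector of the X'Y cross-covariance, soft-thresholded so exactly keepX
# entries survive (LASSO-like selection folded into the covariance
# maximization), followed by regression deflation of both blocks.

# soft-threshold a weight vector so exactly keepX entries survive;
# ties on |u| are broken by absolute value then feature index
soft_threshold_keep <- function(u, keepX) {
  p <- length(u)
  if (keepX >= p) return(u)
  # magnitudes quantized so floating-point near-ties (duplicated columns)
  # follow the documented tie rule: larger |u| first, then feature index
  mag <- signif(abs(u), 12)
  ord <- order(-mag, seq_len(p))
  keep <- ord[seq_len(keepX)]
  thr <- abs(u[ord[keepX + 1L]])
  v <- numeric(p)
  v[keep] <- sign(u[keep]) * pmax(abs(u[keep]) - thr, 0)
  if (max(abs(v[keep])) <= 1e-10 * max(mag)) {
    # a tie spanning the boundary would annihilate the kept set under
    # shrinkage; keep the unshrunk weights instead
    v[keep] <- u[keep]
  }
  v
}

#' Fit a two-class sparse PLS-DA model
#'
#' The class factor is expanded to a centered indicator matrix Y; per
#' component the X weight vector maximizing cov(Xw, Y) is soft-thresholded
#' to `keepX` nonzero entries, the component score is `t = X w`, and both
#' blocks are deflated by regression on `t`. With `keepX = ncol(X)` the
#' model reduces to dense PLS-DA. Class prediction assigns a sample to the
#' class with the nearest centroid in component-score space (Euclidean),
#' and the continuous decision value used for ROC analysis is the
#' difference of squared centroid distances.
#'
#' @param X numeric matrix, samples x features (log intensities).
#' @param y two-level factor of class labels.
#' @param ncomp number of components.
#' @param keepX number of features retained per component (recycled).
#' @param scale autoscale columns to unit variance before fitting (the
#'   usual PLS convention; without it high-variance features dominate the
#'   covariance criterion). Constant columns are left unscaled.
#' @return an `splsda_model`.
#' @export
fit_splsda <- function(X, y, ncomp = 1, keepX = ncol(X), scale = TRUE) {
  if (!is.matrix(X)) X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2L) abort_fmt("y must have exactly 2 classes")
  if (any(table(y) == 0L)) abort_fmt("a class is absent from y")
  if (nrow(X) != length(y)) abort_fmt("X rows and y length differ")
  keepX <- rep_len(keepX, ncomp)
  if (any(keepX < 1L) || any(keepX > ncol(X))) {
    abort_fmt("keepX must lie in [1, ncol(X)]")
  }
  ctr <- colMeans(X)
  scl <- rep(1, ncol(X))
  if (scale) {
    s <- apply(X, 2L, stats::sd)
    scl[s > 1e-12] <- s[s > 1e-12]
  }
  Xc <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  Y <- stats::model.matrix(~ y - 1)
  Yc <- sweep(Y, 2L, colMeans(Y))

  p <- ncol(X)
  loadings <- matrix(0, p, ncomp,
                     dimnames = list(colnames(X), paste0("comp", seq_len(ncomp))))
  c_load <- matrix(0, p, ncomp)
  scores <- matrix(0, nrow(X), ncomp,
                   dimnames = list(rownames(X), paste0("comp", seq_len(ncomp))))
  for (h in seq_len(ncomp)) {
    M <- crossprod(Xc, Yc)
    sv <- svd(M, nu = 1L, nv = 0L)
    u <- soft_threshold_keep(drop(sv$u), keepX[h])
    nu <- sqrt(sum(u^2))
    if (nu < 1e-12) break   # degenerate (deflated to noise): stop early
    u <- u / nu
    t_h <- drop(Xc %*% u)
    tt <- sum(t_h^2)
    c_h <- drop(crossprod(Xc, t_h)) / tt
    d_h <- drop(crossprod(Yc, t_h)) / tt
    Xc <- Xc - tcrossprod(t_h, c_h)
    Yc <- Yc - tcrossprod(t_h, d_h)
    loadings[, h] <- u
    c_load[, h] <- c_h
    scores[, h] <- t_h
  }
  centroids <- rbind(colMeans(scores[y == levels(y)[1L], , drop = FALSE]),
                     colMeans(scores[y == levels(y)[2L], , drop = FALSE]))
  rownames(centroids) <- levels(y)
  structure(list(loadings = loadings, c_loadings = c_load, scores = scores,
                 centroids = centroids, center = ctr, scale = scl,
                 ncomp = ncomp, keepX = keepX, levels = levels(y), y = y),
            class = "splsda_model")
}

#' Project new samples into the component space of a fitted model
#'
#' @param model an `splsda_model`.
#' @param newX samples x features matrix on the same feature set.
#' @return samples x ncomp score matrix.
#' @export
project_splsda <- function(model, newX) {
  if (!is.matrix(newX)) newX <- matrix(newX, nrow = 1)
  Xd <- sweep(sweep(newX, 2L, model$center), 2L, model$scale, "/")
  out <- matrix(0, nrow(newX), model$ncomp)
  for (h in seq_len(model$ncomp)) {
    t_h <- drop(Xd %*% model$loadings[, h])
    Xd <- Xd - tcrossprod(t_h, model$c_loadings[, h])
    out[, h] <- t_h
  }
  out
}

#' @param object an `splsda_model`.
#' @param newX new data matrix (defaults to training scores).
#' @param ... unused.
#' @return list with `class` (factor) and `decision` (higher values favor
#'   the second class level).
#' @rdname fit_splsda
#' @export
predict_splsda <- function(object, newX, ...) {
  sc <- project_splsda(object, newX)
  d1 <- rowSums(sweep(sc, 2L, object$centroids[1L, ])^2)
  d2 <- rowSums(sweep(sc, 2L, object$centroids[2L, ])^2)
  cls <- factor(ifelse(d2 < d1, object$levels[2L], object$levels[1L]),
                levels = object$levels)
  list(class = cls, decision = d1 - d2)
}

#' Features with a nonzero loading on any component
#'
#' @param model an `splsda_model`.
#' @return character vector of feature ids.
#' @export
selected_features <- function(model) {
  rownames(model$loadings)[rowSums(model$loadings != 0) > 0]
}

# stratified indices: for each class, round(fraction * n_class) samples
# (at least 1, at most n_class - 1 so both splits keep both classes)
stratified_split <- function(y, fraction) {
  idx <- integer(0)
  for (lv in levels(y)) {
    pool <- which(y == lv)
    k <- min(max(1L, round(fraction * length(pool))), length(pool) - 1L)
    if (k < 1L) abort_fmt("class '%s' too small for a stratified split", lv)
    idx <- c(idx, sample(pool, k))
  }
  sort(idx)
}

# stratified cross-validation fold assignment
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    pool <- sample(which(y == lv))
    fold[pool] <- rep_len(seq_len(n_folds), length(pool))
  }
  fold
}

#' Tune (ncomp, keepX) by stratified cross-validation
#'
#' Grid search minimizing the cross-validated balanced misclassification
#' rate; ties are broken toward the smallest `keepX`, then the smallest
#' `ncomp`, so pure-noise data yields the most parsimonious model.
#'
#' @param X samples x features matrix.
#' @param y two-level factor.
#' @param ncomp_grid,keepX_grid nonempty candidate grids.
#' @param n_folds cross-validation folds (stratified).
#' @param seed integer seed for fold assignment.
#' @return list with `ncomp`, `keepX`, and the grid of balanced error rates.
#' @export
tune_splsda <- function(X, y, ncomp_grid = 1:2,
                        keepX_grid = c(5, 10, 25, 50),
                        n_folds = 5, seed = 1) {
  y <- factor(y)
  if (!length(ncomp_grid) || !length(keepX_grid)) abort_fmt("empty tuning grid")
  keepX_grid <- sort(unique(pmin(keepX_grid, ncol(X))))
  n_folds <- min(n_folds, min(table(y)))
  if (n_folds < 2L) abort_fmt("too few samples per class for cross-validation")
  ber <- matrix(NA_real_, length(ncomp_grid), length(keepX_grid),
                dimnames = list(paste0("ncomp", ncomp_grid), keepX_grid))
  fold <- with_seed(seed, stratified_folds(y, n_folds))
  for (a in seq_along(ncomp_grid)) {
    for (b in seq_along(keepX_grid)) {
      errs <- vapply(seq_len(n_folds), function(f) {
        tr <- fold != f
        fit <- fit_splsda(X[tr, , drop = FALSE], y[tr],
                          ncomp = ncomp_grid[a], keepX = keepX_grid[b])
        pred <- predict_splsda(fit, X[!tr, , drop = FALSE])$class
        truth <- y[!tr]
        mean(vapply(levels(y), function(lv) {
          if (!any(truth == lv)) return(NA_real_)
          mean(pred[truth == lv] != lv)
        }, numeric(1)), na.rm = TRUE)
      }, numeric(1))
      ber[a, b] <- mean(errs)
    }
  }
  # tie rule: minimal error, then smallest keepX, then smallest ncomp
  best <- which(ber == min(ber), arr.ind = TRUE)
  best <- best[order(best[, "col"], best[, "row"]), , drop = FALSE][1L, ]
  list(ncomp = ncomp_grid[best[["row"]]], keepX = keepX_grid[best[["col"]]],
       ber = ber)
}

#' Stability selection by repeated stratified resampling
#'
#' The model is refitted on many stratified training splits (80% by
#' default); the selection frequency of a feature is the fraction of
#' resamples in which it received a nonzero loading, and the selected panel
#' is the set of features with frequency at or above the threshold (50% by
#' default). Hyperparameters are tuned once on the full data unless given;
#' set `retune = TRUE` to re-tune inside every resample (much slower).
#'
#' @param X samples x features matrix (log intensities).
#' @param y two-level factor.
#' @param n_resamples number of training/test splits.
#' @param train_fraction fraction of each class used for training.
#' @param threshold selection-frequency threshold.
#' @param ncomp,keepX model size; `NULL` triggers tuning via [tune_splsda()].
#' @param ncomp_grid,keepX_grid tuning grids when tuning is needed.
#' @param retune re-tune hyperparameters inside each resample.
#' @param seed integer master seed.
#' @return a `selection_result`: frequencies, selected set, (ncomp, keepX),
#'   accuracy and AUC of the selected panel (via
#'   [evaluate_classification()]), and the resample count.
#' @export
stability_select <- function(X, y, n_resamples = 1000, train_fraction = 0.8,
                             threshold = 0.5, ncomp = NULL, keepX = NULL,
                             ncomp_grid = 1:2, keepX_grid = c(5, 10, 25, 50),
                             retune = FALSE, seed = 1) {
  y <- factor(y)
  if (n_resamples < 1L) abort_fmt("n_resamples must be >= 1")
  if (nlevels(y) != 2L) abort_fmt("y must have exactly 2 classes")
  seeds <- split_seed(seed, 3L)
  if (is.null(ncomp) || is.null(keepX)) {
    tuned <- tune_splsda(X, y, ncomp_grid, keepX_grid, seed = seeds[1L])
    if (is.null(ncomp)) ncomp <- tuned$ncomp
    if (is.null(keepX)) keepX <- tuned$keepX
  }
  counts <- stats::setNames(numeric(ncol(X)), colnames(X))
  with_seed(seeds[2L], {
    for (r in seq_len(n_resamples)) {
      tr <- stratified_split(y, train_fraction)
      fit <- if (retune) {
        tuned_r <- tune_splsda(X[tr, , drop = FALSE], y[tr],
                               ncomp_grid, keepX_grid, seed = NULL)
        fit_splsda(X[tr, , drop = FALSE], y[tr],
                   ncomp = tuned_r$ncomp, keepX = tuned_r$keepX)
      } else {
        fit_splsda(X[tr, , drop = FALSE], y[tr], ncomp = ncomp, keepX = keepX)
      }
      sel <- selected_features(fit)
      counts[sel] <- counts[sel] + 1
    }
  })
  freq <- counts / n_resamples
  selected <- names(freq)[freq >= threshold]
  metrics <- if (length(selected)) {
    evaluate_classification(X, y, selected, ncomp = ncomp,
                            keepX = min(keepX, length(selected)),
                            seed = seeds[3L])
  } else {
    list(accuracy = NA_real_, auc = NA_real_)
  }
  structure(list(frequency = freq, selected = selected, threshold = threshold,
                 ncomp = ncomp, keepX = keepX, n_resamples = n_resamples,
                 accuracy = metrics$accuracy, auc = metrics$auc),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(paste0("stability selection: %d/%d features at threshold %.2f ",
                     "(%d resamples, ncomp=%d, keepX=%d)\n"),
              length(x$selected), length(x$frequency), x$threshold,
              x$n_resamples, x$ncomp, x$keepX))
  cat(sprintf("accuracy %.3f, AUC %.3f\n", x$accuracy, x$auc))
  invisible(x)
}

#' Classification metrics for a peptide panel
#'
#' Accuracy is the fraction of correct class predictions of the model fitted
#' on the full data restricted to the panel. AUC is the mean test-set ROC
#' area over 20 stratified 80/20 train/test splits, using the model's
#' continuous decision value.
#'
#' @param X samples x features matrix.
#' @param y two-level factor.
#' @param features nonempty character vector of panel features.
#' @param ncomp,keepX model size used for the evaluations.
#' @param n_splits number of 80/20 splits for the AUC average.
#' @param seed integer seed.
#' @return list with `accuracy` and `auc`.
#' @export
evaluate_classification <- function(X, y, features, ncomp = 1,
                                    keepX = length(features), n_splits = 20,
                                    seed = 1) {
  if (!length(features)) {
    abort_fmt("empty selection: lower the stability threshold")
  }
  y <- factor(y)
  Xs <- X[, features, drop = FALSE]
  keepX <- min(keepX, ncol(Xs))
  fit <- fit_splsda(Xs, y, ncomp = ncomp, keepX = keepX)
  acc <- mean(predict_splsda(fit, Xs)$class == y)
  aucs <- with_seed(seed, {
    vapply(seq_len(n_splits), function(s) {
      tr <- stratified_split(y, 0.8)
      f <- fit_splsda(Xs[tr, , drop = FALSE], y[tr],
                      ncomp = ncomp, keepX = keepX)
      te <- setdiff(seq_len(nrow(Xs)), tr)
      dec <- predict_splsda(f, Xs[te, , drop = FALSE])$decision
      auc_mann_whitney(dec, y[te] == levels(y)[2L])
    }, numeric(1))
  })
  list(accuracy = acc, auc = mean(aucs, na.rm = TRUE))
}

#' Hierarchical clustering of samples on a selected panel
#'
#' Agglomerative clustering with Euclidean distance and complete linkage;
#' returns the tree, the leaf order and the leaf-ordered data matrix (the
#' table behind a clustered heatmap).
#'
#' @param X samples x features matrix.
#' @param features panel to cluster on (default: all columns). A panel of
#'   fewer than 2 features raises a warning and proceeds.
#' @return list with `hclust`, `order` (sample ids), `ordered_matrix`.
#' @export
cluster_samples <- function(X, features = colnames(X)) {
  if (nrow(X) < 2L) abort_fmt("need at least 2 samples to cluster")
  if (length(features) < 2L) {
    warning("fewer than 2 selected features; clustering on what is available")
  }
  Xs <- X[, features, drop = FALSE]
  hc <- stats::hclust(stats::dist(Xs, method = "euclidean"),
                      method = "complete")
  list(hclust = hc, order = rownames(Xs)[hc$order],
       ordered_matrix = Xs[hc$order, , drop = FALSE])
}
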