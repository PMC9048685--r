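# splsda_stability: sparse PLS-DA, tuning, stability selection, metrics,
# clustering

test_that("dense reduction: keepX = p gives the PLS-DA covariance direction", {
  set.seed(30)
  X <- matrix(rnorm(20 * 8), 20, 8,
              dimnames = list(paste0("s", 1:20), paste0("f", 1:8)))
  y <- factor(rep(c("a", "b"), each = 10))
  fit <- fit_splsda(X, y, ncomp = 1, keepX = 8, scale = FALSE)
  # first loading parallel to t(Xc) %*% Yc's leading singular direction,
  # which for two balanced classes is the class-mean difference direction
  Xc <- scale(X, scale = FALSE)
  d <- colMeans(Xc[y == "b", ]) - colMeans(Xc[y == "a", ])
  cs <- abs(sum(fit$loadings[, 1] * d) /
              sqrt(sum(fit$loadings[, 1]^2) * sum(d^2)))
  expect_equal(cs, 1, tolerance = 1e-8)
  expect_equal(sum(fit$loadings[, 1] != 0), 8L)
})

test_that("sparsity: informative features recovered, tie rule deterministic", {
  set.seed(31)
  n <- 40
  y <- factor(rep(c("a", "b"), each = n / 2))
  X <- matrix(rnorm(n * 100), n)
  X[, 1] <- X[, 1] + ifelse(y == "b", 3, 0)
  X[, 2] <- X[, 2] - ifelse(y == "b", 3, 0)
  colnames(X) <- paste0("f", 1:100); rownames(X) <- paste0("s", 1:n)
  fit <- fit_splsda(X, y, ncomp = 1, keepX = 2)
  expect_setequal(selected_features(fit), c("f1", "f2"))

  # duplicated feature columns: documented tie rule keeps the first index
  Xd <- cbind(X[, 1], X[, 1], X[, 3:10])
  colnames(Xd) <- paste0("g", 1:10); rownames(Xd) <- rownames(X)
  fit_d <- fit_splsda(Xd, y, ncomp = 1, keepX = 1)
  expect_equal(selected_features(fit_d), "g1")
  expect_error(fit_splsda(X, factor(rep("a", n)), 1, 2), "2 classes")
})

test_that("tuning: zero-error point on separable data, tie rule, determinism", {
  set.seed(32)
  n <- 24
  y <- factor(rep(c("a", "b"), each = n / 2))
  X <- matrix(rnorm(n * 30), n)
  X[, 1] <- X[, 1] + ifelse(y == "b", 6, 0)
  colnames(X) <- paste0("f", 1:30); rownames(X) <- paste0("s", 1:n)
  t1 <- tune_splsda(X, y, ncomp_grid = 1:2, keepX_grid = c(1, 5, 10), seed = 4)
  expect_equal(min(t1$ber), 0)
  expect_equal(t1$keepX, 1)      # smallest grid point achieving 0 error
  expect_equal(t1$ncomp, 1)
  # determinism under a fixed seed
  t2 <- tune_splsda(X, y, ncomp_grid = 1:2, keepX_grid = c(1, 5, 10), seed = 4)
  expect_identical(t1[c("ncomp", "keepX")], t2[c("ncomp", "keepX")])

  # pure noise: near-chance error everywhere, most parsimonious model wins
  Xn <- matrix(rnorm(n * 30), n,
               dimnames = list(paste0("s", 1:n), paste0("f", 1:30)))
  tn <- tune_splsda(Xn, y, ncomp_grid = 1:2, keepX_grid = c(1, 5, 10), seed = 4)
  expect_gt(min(tn$ber), 0.2)
  ties <- which(tn$ber == min(tn$ber), arr.ind = TRUE)
  expect_equal(tn$keepX, c(1, 5, 10)[min(ties[, "col"])])
})

test_that("stability selection: frequencies, threshold semantics, recovery", {
  fix <- planted_cohort(n_features = 120, n_planted = 5, log2fc = 2,
                        n_per_group = c(15, 15), seed = 301)
  X <- log_transform(fix$cohort$intensity)
  y <- fix$cohort$group
  sel <- stability_select(X, y, n_resamples = 50, ncomp = 1, keepX = 5,
                          seed = 33)
  # frequencies are multiples of 1/R in [0, 1]
  expect_true(all(sel$frequency >= 0 & sel$frequency <= 1))
  expect_true(all(abs(sel$frequency * 50 - round(sel$frequency * 50)) < 1e-9))
  # selected set = thresholded frequencies, monotone in the threshold
  expect_setequal(sel$selected,
                  names(sel$frequency)[sel$frequency >= 0.5])
  stricter <- names(sel$frequency)[sel$frequency >= 0.8]
  expect_true(all(stricter %in% sel$selected))
  # planted features dominate the panel
  expect_gte(mean(fix$planted %in% sel$selected), 0.8)
  # bitwise reproducibility of the seeded end-to-end run
  sel2 <- stability_select(X, y, n_resamples = 50, ncomp = 1, keepX = 5,
                           seed = 33)
  expect_identical(sel$frequency, sel2$frequency)
  expect_identical(sel$selected, sel2$selected)
  expect_equal(sel$accuracy, sel2$accuracy)
  expect_error(stability_select(X, y, n_resamples = 0), "n_resamples")
})

test_that("null cohort selects no more than the planted alternative", {
  ref <- default_reference_distribution(120, seed = 302)
  co0 <- generate_cohort(ref, c(15, 15), seed = 303)
  sel0 <- stability_select(log_transform(co0$intensity), co0$group,
                           n_resamples = 50, ncomp = 1, keepX = 5, seed = 33)
  fix <- planted_cohort(n_features = 120, n_planted = 5, log2fc = 2,
                        n_per_group = c(15, 15), seed = 301)
  sel1 <- stability_select(log_transform(fix$cohort$intensity),
                           fix$cohort$group, n_resamples = 50, ncomp = 1,
                           keepX = 5, seed = 33)
  expect_lte(length(sel0$selected), length(sel1$selected))
  # expected selection frequency of a null feature is keepX / p, far from 1
  expect_lt(mean(sel0$frequency), 0.3)
})

test_that("classification metrics: separable, constructed and null cases", {
  set.seed(34)
  n <- 40
  y <- factor(rep(c("a", "b"), each = n / 2))
  # linearly separable toy data
  X <- matrix(rnorm(n * 10), n)
  X[, 1] <- ifelse(y == "b", 5, 0) + rnorm(n, sd = 0.1)
  colnames(X) <- paste0("f", 1:10); rownames(X) <- paste0("s", 1:n)
  ev <- evaluate_classification(X, y, colnames(X), ncomp = 1, seed = 5)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$auc, 1)

  # single feature equal to the class indicator plus tiny noise
  X1 <- matrix(as.numeric(y == "b") + rnorm(n, sd = 0.05), n, 1,
               dimnames = list(paste0("s", 1:n), "f1"))
  ev1 <- evaluate_classification(X1, y, "f1", ncomp = 1, seed = 5)
  expect_gte(ev1$accuracy, 0.95)

  # permuted labels: AUC within the null band
  set.seed(35)
  Xn <- matrix(rnorm(60 * 30), 60,
               dimnames = list(paste0("s", 1:60), paste0("f", 1:30)))
  yn <- factor(sample(rep(c("a", "b"), each = 30)))
  evn <- evaluate_classification(Xn, yn, colnames(Xn), ncomp = 1, seed = 6)
  expect_gt(evn$auc, 0.35)
  expect_lt(evn$auc, 0.65)

  expect_error(evaluate_classification(X, y, character(0)), "empty selection")
})

test_that("clustering matches brute-force complete linkage and separates blobs", {
  set.seed(36)
  # two tight, well-separated clouds: top split equals the true bipartition
  X <- rbind(matrix(rnorm(5 * 4, 0, 0.1), 5),
             matrix(rnorm(5 * 4, 10, 0.1), 5))
  dimnames(X) <- list(paste0("s", 1:10), paste0("f", 1:4))
  cl <- cluster_samples(X)
  top <- stats::cutree(cl$hclust, k = 2)
  expect_equal(length(unique(top[1:5])), 1L)
  expect_equal(length(unique(top[6:10])), 1L)
  expect_true(all(top[1:5] != top[6:10]))
  # merge heights nondecreasing
  expect_true(all(diff(cl$hclust$height) >= -1e-12))
  # ordered matrix is the data re-indexed by leaf order
  expect_equal(cl$ordered_matrix, X[cl$order, ])

  # brute-force complete-linkage enumeration on 4 points
  Y <- matrix(c(0, 0, 1, 0, 6, 0, 6.5, 0), 4, 2, byrow = TRUE,
              dimnames = list(paste0("q", 1:4), c("x", "y")))
  hy <- cluster_samples(Y)$hclust
  # first merges: {q1,q2} at 1 and {q3,q4} at 0.5; final at max dist 6.5
  expect_equal(sort(hy$height), c(0.5, 1, 6.5), tolerance = 1e-12)
  expect_warning(cluster_samples(X, features = "f1"), "fewer than 2")
})
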