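# Empirical power / sample-size estimation for differential metaproteomics:
# simulate a large two-group reference population with injected log2
# fold-change effects, repeatedly subsample N patients per group, test every
# feature, FDR-correct, and record how often the injected features are
# recovered.

#' Build a simulated reference population with injected effects
#'
#' Delegates to [generate_cohort()]: two equal groups drawn from the
#' reference distribution, with `n_per_tier` differentially abundant
#' features per log2 fold-change tier injected in group B. Perturbed
#' features are drawn among features with detection probability >= 0.2 (an
#' effect on an almost-never-detected peptide is unobservable at any N).
#'
#' @param ref a `reference_distribution`.
#' @param n_per_group individuals per group (2 groups).
#' @param log2fc_tiers effect-size tiers.
#' @param n_per_tier injected features per tier.
#' @param seed integer master seed.
#' @return a `reference_population` list: `intensity`, `group`, `truth`
#'   (data frame feature_id / log2fc tier), `effects`.
#' @export
build_reference_population <- function(ref, n_per_group = 5000,
                                       log2fc_tiers = c(1.25, 1.5, 2),
                                       n_per_tier = 100, seed = 1) {
  stopifnot(inherits(ref, "reference_distribution"))
  n_eff <- length(log2fc_tiers) * n_per_tier
  eligible <- ref$feature_id[ref$pi >= 0.2]
  if (length(eligible) < n_eff) {
    abort_fmt("need >= %d features with detection probability >= 0.2 (have %d)",
              n_eff, length(eligible))
  }
  seeds <- split_seed(seed, 2L)
  chosen <- with_seed(seeds[1L], sample(eligible, n_eff))
  eff <- effect_spec(chosen, rep(log2fc_tiers, each = n_per_tier),
                     up_group = "B")
  cohort <- generate_cohort(ref, n_per_group = c(n_per_group, n_per_group),
                            effects = eff, seed = seeds[2L])
  truth <- data.frame(feature_id = eff$feature_id, log2fc = eff$log2fc,
                      stringsAsFactors = FALSE)
  structure(list(intensity = cohort$intensity, group = cohort$group,
                 truth = truth, effects = eff, seed = seed),
            class = "reference_population")
}

# vectorized two-sided Wilcoxon rank-sum p-values for every column of X
# (normal approximation with tie correction and continuity correction;
# zero-inflated intensity data is tie-heavy, making exact enumeration
# unavailable anyway)
rank_sum_pvalues <- function(X, in_a) {
  n <- nrow(X)
  n1 <- sum(in_a)
  n2 <- n - n1
  R <- apply(X, 2L, rank)
  if (is.null(dim(R))) R <- matrix(R, nrow = n)
  W <- colSums(R[in_a, , drop = FALSE]) - n1 * (n1 + 1) / 2
  tie_term <- apply(X, 2L, function(col) {
    t <- tabulate(match(col, unique(col)))
    sum(t^3 - t)
  })
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- numeric(ncol(X))
  ok <- sigma2 > 0
  dev <- W - mu
  z[ok] <- (dev[ok] - sign(dev[ok]) * 0.5) / sqrt(sigma2[ok])
  p <- 2 * stats::pnorm(-abs(z))
  p[!ok] <- 1
  pmin(p, 1)
}

# vectorized Welch t-test p-values per column (comparison mode)
t_test_pvalues <- function(X, in_a) {
  xa <- X[in_a, , drop = FALSE]
  xb <- X[!in_a, , drop = FALSE]
  na <- nrow(xa); nb <- nrow(xb)
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- apply(xa, 2L, stats::var) / na
  vb <- apply(xb, 2L, stats::var) / nb
  se2 <- va + vb
  ok <- se2 > 0
  t <- numeric(ncol(X))
  df <- rep(1, ncol(X))
  t[ok] <- (ma[ok] - mb[ok]) / sqrt(se2[ok])
  df[ok] <- se2[ok]^2 / (va[ok]^2 / (na - 1) + vb[ok]^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[!ok] <- 1
  p
}

#' Estimate empirical power over a sample-size grid
#'
#' For each N on the grid and each of `n_subsamples` replicates: draw N
#' individuals per group without replacement from the reference population,
#' test every feature for a between-group difference on log2 intensities
#' (two-sided Wilcoxon rank-sum by default), adjust p-values by
#' Benjamini-Hochberg over all features, and record which injected features
#' are rejected. Power for a (N, log2fc) cell is the mean per-feature
#' rejection rate of the tier's features over the replicates. The false
#' rejection rate of the unperturbed features is tracked per N.
#'
#' @param population a `reference_population`.
#' @param N_grid patient counts per group (each >= 2, at most group size).
#' @param n_subsamples replicates per N.
#' @param alpha FDR level.
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @param seed integer master seed.
#' @return a `power_curve` data frame (columns `N`, `log2fc`, `power`) with
#'   attributes `alpha`, `n_subsamples`, `test`, `fpr` (per-N false
#'   rejection rate among null features).
#' @export
estimate_power <- function(population, N_grid = c(15, 30, 50, 70, 100),
                           n_subsamples = 1000, alpha = 0.05,
                           test = c("wilcoxon", "t"), seed = 1) {
  stopifnot(inherits(population, "reference_population"))
  test <- match.arg(test)
  if (any(N_grid < 2L)) abort_fmt("every N must be >= 2")
  sizes <- table(population$group)
  if (max(N_grid) > min(sizes)) {
    abort_fmt("max(N_grid) = %d exceeds the group size %d",
              max(N_grid), min(sizes))
  }
  X <- log_transform(population$intensity)        # log2(x + 1)
  idx_a <- which(population$group == "A")
  idx_b <- which(population$group == "B")
  truth_idx <- match(population$truth$feature_id, colnames(X))
  tiers <- sort(unique(population$truth$log2fc))
  null_idx <- setdiff(seq_len(ncol(X)), truth_idx)
  pfun <- if (test == "wilcoxon") rank_sum_pvalues else t_test_pvalues

  seeds <- split_seed(seed, length(N_grid))
  rows <- list()
  fpr <- stats::setNames(numeric(length(N_grid)), N_grid)
  for (g in seq_along(N_grid)) {
    N <- N_grid[g]
    hits <- numeric(nrow(population$truth))
    false_rej <- 0
    with_seed(seeds[g], {
      for (s in seq_len(n_subsamples)) {
        take <- c(sample(idx_a, N), sample(idx_b, N))
        Xs <- X[take, , drop = FALSE]
        p <- pfun(Xs, rep(c(TRUE, FALSE), each = N))
        padj <- stats::p.adjust(p, method = "BH")
        rej <- padj < alpha
        hits <- hits + rej[truth_idx]
        false_rej <- false_rej + mean(rej[null_idx])
      }
    })
    hits <- hits / n_subsamples
    fpr[g] <- false_rej / n_subsamples
    for (fc in tiers) {
      rows[[length(rows) + 1L]] <- data.frame(
        N = N, log2fc = fc,
        power = mean(hits[population$truth$log2fc == fc]))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(N = integer(0), log2fc = numeric(0), power = numeric(0))
  attr(out, "alpha") <- alpha
  attr(out, "n_subsamples") <- n_subsamples
  attr(out, "test") <- test
  attr(out, "fpr") <- fpr
  class(out) <- c("power_curve", "data.frame")
  out
}

#' Smallest N per effect tier reaching a target power
#'
#' @param curve a `power_curve`.
#' @param target target power (default 0.8).
#' @return data frame with `log2fc` and `min_N` (`NA` when the target is not
#'   reached anywhere on the grid).
#' @export
minimum_n_for_power <- function(curve, target = 0.8) {
  if (!nrow(curve)) abort_fmt("empty power curve")
  tiers <- sort(unique(curve$log2fc))
  min_n <- vapply(tiers, function(fc) {
    sub <- curve[curve$log2fc == fc, ]
    sub <- sub[order(sub$N), ]
    hit <- which(sub$power >= target)
    if (length(hit)) sub$N[hit[1L]] else NA_integer_
  }, numeric(1))
  data.frame(log2fc = tiers, min_N = as.integer(min_n))
}
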