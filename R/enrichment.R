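# Over-representation of taxonomic/functional categories in a selected
# peptide set against the full peptide background: one-sided Fisher tests,
# a permutation-based empirical null (category labels shuffled across the
# background, preserving category sizes), and a covariate-residualized
# sensitivity analysis rerunning the whole selection + enrichment pipeline.

#' Fisher over-representation of annotation categories in a selected set
#'
#' For every category at every requested level, a 2x2 table (selected vs.
#' not x in-category vs. not over the background peptide set) is tested
#' one-sided for over-representation with Fisher's exact test. When an
#' intensity matrix and groups are supplied, the direction of each category
#' ("higher in" which group) is the group with the larger mean summed
#' intensity of the category's selected peptides. Categories supported by
#' fewer than 2 selected peptides are reported but flagged `low_support`.
#'
#' @param selected character vector of selected feature ids (subset of
#'   `background`).
#' @param ann validated annotation table covering the background.
#' @param background character vector of all candidate feature ids.
#' @param levels annotation levels to test (default: all ranks + function).
#' @param m optional intensity matrix for direction calls.
#' @param groups optional named A/B factor (as from [assign_groups()]).
#' @param group_labels optional labels used in the `direction` column.
#' @return data frame: level, category, n_selected, n_background,
#'   expected_prop, fisher_p, direction, low_support.
#' @export
category_enrichment <- function(selected, ann, background,
                                levels = ENRICHMENT_LEVELS,
                                m = NULL, groups = NULL,
                                group_labels = c(A = "A", B = "B")) {
  if (!length(selected)) abort_fmt("empty selected set")
  if (!all(selected %in% background)) {
    abort_fmt("selected features must be a subset of the background")
  }
  bad <- setdiff(levels, ENRICHMENT_LEVELS)
  if (length(bad)) abort_fmt("unknown enrichment level '%s'", bad[1L])
  out <- list()
  n_bg <- length(background)
  n_sel <- length(selected)
  for (lv in levels) {
    cats <- feature_categories(ann, lv)[background]
    for (cat in sort(unique(cats[!is.na(cats)]))) {
      in_cat <- !is.na(cats) & cats == cat
      K <- sum(in_cat)
      a <- sum(selected %in% background[in_cat])
      tab <- matrix(c(a, n_sel - a, K - a, n_bg - n_sel - (K - a)), 2L)
      p <- stats::fisher.test(tab, alternative = "greater")$p.value
      dir <- NA_character_
      if (!is.null(m) && !is.null(groups) && a > 0L) {
        feats <- intersect(selected, background[in_cat])
        tot <- rowSums(m[, feats, drop = FALSE])
        mA <- mean(tot[names(groups)[groups == "A"]])
        mB <- mean(tot[names(groups)[groups == "B"]])
        dir <- if (mA >= mB) group_labels[["A"]] else group_labels[["B"]]
      }
      out[[length(out) + 1L]] <- data.frame(
        level = lv, category = cat, n_selected = a, n_background = K,
        expected_prop = K / n_bg, fisher_p = p, direction = dir,
        low_support = a < 2L, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Empirical enrichment p-values by category-label permutation
#'
#' Under the null of no association, peptides are assigned to a random
#' category: each permutation shuffles the category labels across the
#' background (preserving category sizes exactly) and recomputes the
#' selected-set count per category. The empirical p-value is
#' `(1 + #{permuted count >= observed}) / (B + 1)`.
#'
#' @inheritParams category_enrichment
#' @param B number of permutations.
#' @param seed integer seed.
#' @return data frame: level, category, n_selected, empirical_p.
#' @export
empirical_enrichment <- function(selected, ann, background,
                                 levels = ENRICHMENT_LEVELS,
                                 B = 10000, seed = 1) {
  if (B < 1L) abort_fmt("B must be >= 1")
  if (!length(selected)) abort_fmt("empty selected set")
  sel_idx <- match(selected, background)
  if (anyNA(sel_idx)) abort_fmt("selected features must be a subset of the background")
  n_bg <- length(background)
  n_sel <- length(selected)
  out <- list()
  with_seed(seed, {
    for (lv in levels) {
      cats <- feature_categories(ann, lv)[background]
      ucats <- sort(unique(cats[!is.na(cats)]))
      if (!length(ucats)) next
      cat_int <- match(cats, ucats)           # NA for unannotated peptides
      obs <- tabulate(cat_int[sel_idx], nbins = length(ucats))
      exceed <- integer(length(ucats))
      has_cat <- which(!is.na(cat_int))
      lab <- cat_int[has_cat]
      for (b in seq_len(B)) {
        # shuffling labels over the background and reading the selected
        # positions == drawing n_sel positions at random
        perm <- cat_int
        perm[has_cat] <- sample(lab)
        cnt <- tabulate(perm[sel_idx], nbins = length(ucats))
        exceed <- exceed + (cnt >= obs)
      }
      out[[length(out) + 1L]] <- data.frame(
        level = lv, category = ucats, n_selected = obs,
        empirical_p = (1 + exceed) / (B + 1), stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Replace intensities by residuals of a covariate regression
#'
#' Each feature's (log) intensity vector is regressed on the covariate
#' design by least squares and replaced by the residuals. Factors are
#' expanded to indicators; rank-deficient (collinear) designs drop the
#' redundant columns with a warning.
#'
#' @param m numeric matrix, samples in rows.
#' @param covariates data frame of covariates, rows aligned with `m`.
#' @return residual matrix, same dimnames.
#' @export
residualize <- function(m, covariates) {
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L) return(m)
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == nrow(m))
  design <- stats::model.matrix(~ ., data = covariates)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    warning(sprintf("collinear covariate design: dropped %d redundant column(s)",
                    ncol(design) - qrd$rank))
  }
  res <- qr.resid(qrd, m)
  dimnames(res) <- dimnames(m)
  res
}

#' Main + sensitivity enrichment pipeline for one clinical comparison
#'
#' The main analysis runs stability selection on log intensities and
#' computes empirical enrichment of the selected panel. The sensitivity
#' analysis repeats the whole procedure starting from the residuals of the
#' regression of log intensities on the supplied covariates (all clinical
#' characteristics except the one defining the comparison). Both empirical
#' p-value columns are merged per category; a category is flagged
#' significant when its empirical p is below `alpha` in the main and/or the
#' sensitivity analysis, and `significant_both` when below in both.
#'
#' @param m intensity matrix (raw scale; log-transformed internally).
#' @param clinical validated clinical table.
#' @param comparison a [comparison_spec()].
#' @param ann annotation table covering the features of `m`.
#' @param covariates character vector of clinical covariates to residualize
#'   on (must exclude the comparison variable); default: all others.
#' @param levels annotation levels to test.
#' @param n_resamples,threshold,ncomp,keepX passed to [stability_select()].
#' @param B permutations for the empirical null.
#' @param alpha significance level on the empirical p-values.
#' @param seed integer master seed.
#' @return an `enrichment_result` list: `table` (merged per-category data
#'   frame), `selected_main`, `selected_sensitivity`, `groups`.
#' @export
sensitivity_enrichment <- function(m, clinical, comparison, ann,
                                   covariates = NULL,
                                   levels = ENRICHMENT_LEVELS,
                                   n_resamples = 200, threshold = 0.5,
                                   ncomp = 1, keepX = NULL,
                                   B = 1000, alpha = 0.05, seed = 1) {
  validate_intensity_matrix(m)
  stopifnot(inherits(comparison, "comparison_spec"))
  all_covs <- setdiff(c("gender", "age", "site", "stage", "grade", "tils"),
                      comparison$variable)
  if (is.null(covariates)) covariates <- all_covs
  if (comparison$variable %in% covariates) {
    abort_fmt("covariates must exclude the comparison variable '%s'",
              comparison$variable)
  }
  idx <- match(rownames(m), clinical$sample_id)
  if (anyNA(idx)) abort_fmt("sample '%s' missing from the clinical table",
                            rownames(m)[which(is.na(idx))[1L]])
  clin <- clinical[idx, ]
  groups <- assign_groups(clin, comparison)
  X <- log_transform(m)
  seeds <- split_seed(seed, 4L)
  run_one <- function(Xin, sel_seed, perm_seed) {
    sel <- stability_select(Xin, groups, n_resamples = n_resamples,
                            threshold = threshold, ncomp = ncomp,
                            keepX = keepX, seed = sel_seed)
    if (!length(sel$selected)) {
      return(list(selection = sel, enr = NULL))
    }
    fis <- category_enrichment(sel$selected, ann, colnames(m), levels,
                               m = m, groups = groups,
                               group_labels = comparison$group_labels)
    emp <- empirical_enrichment(sel$selected, ann, colnames(m), levels,
                                B = B, seed = perm_seed)
    list(selection = sel,
         enr = merge(fis, emp[, c("level", "category", "empirical_p")],
                     by = c("level", "category"), sort = FALSE))
  }
  main <- run_one(X, seeds[1L], seeds[2L])
  Xres <- residualize(X, clin[, covariates, drop = FALSE])
  sens <- if (length(covariates)) run_one(Xres, seeds[3L], seeds[4L]) else
    run_one(X, seeds[1L], seeds[2L])   # zero covariates: identical to main

  tab <- NULL
  if (!is.null(main$enr)) {
    tab <- main$enr
    names(tab)[names(tab) == "empirical_p"] <- "empirical_p_main"
    if (!is.null(sens$enr)) {
      s <- sens$enr[, c("level", "category", "empirical_p")]
      names(s)[3L] <- "empirical_p_sensitivity"
      tab <- merge(tab, s, by = c("level", "category"), all.x = TRUE,
                   sort = FALSE)
    } else {
      tab$empirical_p_sensitivity <- NA_real_
    }
    tab$significant <- (tab$empirical_p_main < alpha) |
      (!is.na(tab$empirical_p_sensitivity) & tab$empirical_p_sensitivity < alpha)
    tab$significant_both <- (tab$empirical_p_main < alpha) &
      !is.na(tab$empirical_p_sensitivity) & tab$empirical_p_sensitivity < alpha
    tab <- tab[order(tab$empirical_p_main), ]
    rownames(tab) <- NULL
  }
  structure(list(table = tab, selected_main = main$selection$selected,
                 selected_sensitivity = sens$selection$selected,
                 groups = groups, comparison = comparison, alpha = alpha),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment for %s: %d main-selected, %d sensitivity-selected peptides\n",
              x$comparison$variable, length(x$selected_main),
              length(x$selected_sensitivity)))
  if (!is.null(x$table)) {
    sig <- x$table[x$table$significant, , drop = FALSE]
    cat(sprintf("%d categor%s significant at alpha = %g\n", nrow(sig),
                if (nrow(sig) == 1) "y" else "ies", x$alpha))
  }
  invisible(x)
}
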