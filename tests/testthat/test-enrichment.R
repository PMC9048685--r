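# enrichment: Fisher over-representation, permutation empirical p-values,
# residualized sensitivity analysis

test_that("Fisher enrichment matches the hypergeometric tail by hand", {
  toy <- enrichment_toy()
  # 4/10/20 case: select 10 peptides of which 4 from the 10-member genus
  selected <- c(toy$background[1:4], toy$background[11:16])
  res <- category_enrichment(selected, toy$ann, toy$background,
                             levels = "genus")
  a_row <- res[res$category == "GenusA", ]
  p_hand <- phyper(4 - 1, 10, 40, 10, lower.tail = FALSE)
  expect_equal(a_row$fisher_p, p_hand, tolerance = 1e-12)
  expect_equal(a_row$n_selected, 4L)
  expect_equal(a_row$expected_prop, 10 / 50)
  expect_false(a_row$low_support)

  # proportions identical in selected and background: p close to 1
  prop_sel <- c(toy$background[1:2], toy$background[11:18])
  res2 <- category_enrichment(prop_sel, toy$ann, toy$background,
                              levels = "genus")
  expect_gt(res2[res2$category == "GenusA", "fisher_p"], 0.5)

  # selected disjoint from the category: over-representation p = 1
  res3 <- category_enrichment(toy$background[11:20], toy$ann, toy$background,
                              levels = "genus")
  expect_equal(res3[res3$category == "GenusA", "fisher_p"], 1)
  expect_error(category_enrichment(character(0), toy$ann, toy$background),
               "empty")
})

test_that("direction reports the group with higher selected-peptide abundance", {
  toy <- enrichment_toy()
  m <- matrix(1, 6, 50, dimnames = list(paste0("s", 1:6), toy$background))
  groups <- factor(rep(c("A", "B"), each = 3), levels = c("A", "B"))
  names(groups) <- rownames(m)
  m[groups == "B", 1:10] <- 9    # genus A peptides higher in group B
  res <- category_enrichment(toy$background[1:10], toy$ann, toy$background,
                             levels = "genus", m = m, groups = groups,
                             group_labels = c(A = "low", B = "high"))
  expect_equal(res[res$category == "GenusA", "direction"], "high")
})

test_that("empirical p converges to the hypergeometric tail (3 MC SE)", {
  toy <- enrichment_toy()
  selected <- c(toy$background[1:4], toy$background[11:16])
  emp <- empirical_enrichment(selected, toy$ann, toy$background,
                              levels = "genus", B = 10000, seed = 9)
  p_exact <- phyper(4 - 1, 10, 40, 10, lower.tail = FALSE)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 10000)
  a_p <- emp[emp$category == "GenusA", "empirical_p"]
  expect_lt(abs(a_p - p_exact), 3 * mc_se + 2 / 10001)
  # bounds: empirical p in [1/(B+1), 1]
  expect_true(all(emp$empirical_p >= 1 / 10001 & emp$empirical_p <= 1))
  # determinism
  emp2 <- empirical_enrichment(selected, toy$ann, toy$background,
                               levels = "genus", B = 10000, seed = 9)
  expect_identical(emp$empirical_p, emp2$empirical_p)
})

test_that("single all-covering category yields empirical p = 1", {
  bg <- sprintf("x%02d", 1:20)
  ann <- make_annotation(bg, superkingdom = "Bacteria", phylum = "OnlyPhylum")
  emp <- empirical_enrichment(bg[1:5], ann, bg, levels = "phylum",
                              B = 200, seed = 1)
  expect_equal(emp$empirical_p, 1)
})

test_that("empirical p is monotone in enrichment strength", {
  toy <- enrichment_toy()
  # same selected-set size, increasing overlap with the 10-member genus
  ps <- vapply(c(2, 5, 8), function(k) {
    sel <- c(toy$background[seq_len(k)], toy$background[10 + seq_len(10 - k)])
    emp <- empirical_enrichment(sel, toy$ann, toy$background,
                                levels = "genus", B = 2000, seed = 13)
    emp[emp$category == "GenusA", "empirical_p"]
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("residualize: identity without covariates, drops collinear columns", {
  set.seed(40)
  m <- matrix(rnorm(20 * 5), 20,
              dimnames = list(paste0("s", 1:20), paste0("f", 1:5)))
  expect_identical(residualize(m, NULL), m)
  covs <- data.frame(age = rnorm(20))
  res <- residualize(m, covs)
  # residuals orthogonal to the covariate
  expect_lt(max(abs(crossprod(covs$age, res))), 1e-8)
  expect_lt(max(abs(colMeans(res))), 1e-10)
  covs2 <- data.frame(a = covs$age, b = 2 * covs$age)
  expect_warning(res2 <- residualize(m, covs2), "collinear")
  expect_equal(res2, res, tolerance = 1e-10)
})

test_that("confounded effect is significant in main, removed in sensitivity", {
  # features 1:10 (a single genus) driven by age, not by the group per se;
  # the group assignment follows age, so the main analysis selects them but
  # the age-residualized sensitivity analysis must not
  set.seed(41)
  n <- 30
  ids <- sprintf("s%02d", 1:n)
  age <- seq(40, 80, length.out = n)
  clin <- reference_cohort()[rep(1:24, length.out = n), ]
  clin$sample_id <- ids
  clin$age <- age
  clin$stage <- ifelse(seq_len(n) <= n / 2, "I", "IV")  # group A = young half
  m <- matrix(rexp(n * 40, rate = 1e-3), n,
              dimnames = list(ids, sprintf("f%02d", 1:40)))
  m[, 1:10] <- m[, 1:10] * exp(0.1 * (age - 60))  # age-driven abundance
  ann <- make_annotation(colnames(m), superkingdom = "Bacteria",
                         phylum = "P", class = "C", order = "O", family = "F",
                         genus = rep(c("Confounded", "Other"), c(10, 30)))
  res <- sensitivity_enrichment(m, clin, comparison_spec("stage"), ann,
                                covariates = "age", levels = "genus",
                                n_resamples = 60, ncomp = 1, keepX = 10,
                                B = 500, seed = 11)
  tab <- res$table
  conf <- tab[tab$category == "Confounded", ]
  expect_equal(nrow(conf), 1L)
  expect_lt(conf$empirical_p_main, 0.05)
  expect_true(is.na(conf$empirical_p_sensitivity) ||
                conf$empirical_p_sensitivity > 0.05)
})

test_that("pure-noise covariates leave the sensitivity analysis ~ the main", {
  fix <- planted_cohort(n_features = 80, n_planted = 8, log2fc = 2.5,
                        n_per_group = c(12, 12), seed = 401)
  co <- fix$cohort
  # make the stage variable equal to the true group so selection works,
  # and note age/gender/site are independent noise by construction
  clin <- co$clinical
  clin$stage <- ifelse(co$group == "A", "I", "IV")
  ann <- make_annotation(colnames(co$intensity), superkingdom = "Bacteria",
                         phylum = "P", class = "C", order = "O", family = "F",
                         genus = rep(c("Planted", "Rest"), c(8, 72)))
  res <- sensitivity_enrichment(co$intensity, clin, comparison_spec("stage"),
                                ann, covariates = c("age", "gender"),
                                levels = "genus", n_resamples = 60,
                                ncomp = 1, keepX = 8, B = 500, seed = 12)
  tab <- res$table
  planted_row <- tab[tab$category == "Planted", ]
  expect_lt(planted_row$empirical_p_main, 0.05)
  expect_lt(planted_row$empirical_p_sensitivity, 0.05)
  expect_true(planted_row$significant)
  expect_true(planted_row$significant_both)

  # zero covariates: sensitivity identical to main
  res0 <- sensitivity_enrichment(co$intensity, clin, comparison_spec("stage"),
                                 ann, covariates = character(0),
                                 levels = "genus", n_resamples = 60,
                                 ncomp = 1, keepX = 8, B = 500, seed = 12)
  expect_identical(res0$table$empirical_p_main,
                   res0$table$empirical_p_sensitivity)
})

test_that("permutation preserves per-category counts exactly", {
  # selecting the whole background makes every permuted count equal the
  # category size, so empirical p must be exactly 1 for every category iff
  # the shuffle preserves category sizes
  toy <- enrichment_toy()
  emp <- empirical_enrichment(toy$background, toy$ann, toy$background,
                              levels = "genus", B = 500, seed = 3)
  expect_equal(emp$empirical_p, rep(1, nrow(emp)))
  expect_equal(emp$n_selected, c(10L, 40L))
})
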