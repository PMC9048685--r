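# synthetic_data: reference fitting, cohort generation, annotations

test_that("fit_reference_distribution closed forms and error cases", {
  m <- rbind(c(3, 0, 0), c(3, 0, 2), c(3, 0, 8))
  dimnames(m) <- list(paste0("s", 1:3), paste0("f", 1:3))
  ref <- fit_reference_distribution(m, sigma_floor = 0.1)
  # constant detected feature: pi = 1, mu = log v, sigma at the floor
  expect_equal(ref$pi[1], 1)
  expect_equal(ref$mu[1], log(3))
  expect_equal(ref$sigma[1], 0.1)
  # never-detected feature
  expect_equal(ref$pi[2], 0)
  # partially detected feature
  expect_equal(ref$pi[3], 2 / 3)
  expect_equal(ref$mu[3], mean(log(c(2, 8))))
  expect_error(fit_reference_distribution(m[1, , drop = FALSE]), "2 samples")
})

test_that("parameter recovery from a large generated cohort (3 SE)", {
  ref <- data.frame(feature_id = c("a", "b", "c"),
                    pi = c(1, 0.6, 0.25),
                    mu = c(10, 12, 14), sigma = c(0.5, 1, 0.8))
  class(ref) <- c("reference_distribution", "data.frame")
  n <- 2000
  co <- generate_cohort(ref, c(n / 2, n / 2), seed = 77)
  fit <- fit_reference_distribution(co$intensity)
  for (j in 1:3) {
    se_pi <- sqrt(ref$pi[j] * (1 - ref$pi[j]) / n)
    expect_lt(abs(fit$pi[j] - ref$pi[j]), max(3 * se_pi, 1e-9))
    n_det <- round(n * ref$pi[j])
    expect_lt(abs(fit$mu[j] - ref$mu[j]), 3 * ref$sigma[j] / sqrt(n_det))
    expect_lt(abs(fit$sigma[j] - ref$sigma[j]),
              3 * ref$sigma[j] / sqrt(2 * (n_det - 1)))
  }
})

test_that("cohort generation is deterministic and honors the effect spec", {
  ref <- default_reference_distribution(50, seed = 5)
  a <- generate_cohort(ref, c(6, 6), seed = 42)
  b <- generate_cohort(ref, c(6, 6), seed = 42)
  expect_identical(a$intensity, b$intensity)
  expect_identical(a$clinical, b$clinical)
  expect_false(identical(a$intensity,
                         generate_cohort(ref, c(6, 6), seed = 43)$intensity))

  # pi = 0 feature gives an all-zero column
  ref0 <- ref; ref0$pi[1] <- 0
  co0 <- generate_cohort(ref0, c(6, 6), seed = 1)
  expect_true(all(co0$intensity[, 1] == 0))

  # unknown effect features rejected
  expect_error(generate_cohort(ref, c(3, 3),
                               effects = effect_spec("nope", 2), seed = 1),
               "not in the feature space")
})

test_that("log2FC = 2 on an always-detected feature: GM ratio in [3.5, 4.5]", {
  ref <- data.frame(feature_id = "f1", pi = 1, mu = 12, sigma = 0.8)
  class(ref) <- c("reference_distribution", "data.frame")
  co <- generate_cohort(ref, c(500, 500), effects = effect_spec("f1", 2),
                        seed = 8)
  gm <- function(x) exp(mean(log(x)))
  ratio <- gm(co$intensity[co$group == "B", 1]) /
    gm(co$intensity[co$group == "A", 1])
  expect_gt(ratio, 3.5)
  expect_lt(ratio, 4.5)
})

test_that("effect injection perturbs only the designated features/group", {
  ref <- default_reference_distribution(40, seed = 9)
  eff <- effect_spec(ref$feature_id[1:3], 2, up_group = "B")
  with_eff <- generate_cohort(ref, c(10, 10), effects = eff, seed = 55)
  without <- generate_cohort(ref, c(10, 10), seed = 55)
  # group A rows and untouched features are bitwise identical across seeds
  expect_identical(with_eff$intensity[with_eff$group == "A", ],
                   without$intensity[without$group == "A", ])
  expect_identical(with_eff$intensity[, -(1:3)], without$intensity[, -(1:3)])
})

test_that("annotation generation: truncation, single-genus and frequencies", {
  ids <- sprintf("f%04d", 1:400)
  # truncation probability 1 at genus: nothing below family survives
  ann <- generate_annotations(ids, human_fraction = 0,
                              truncation = c(genus = 1), seed = 2)
  expect_true(all(is.na(ann$genus)))
  expect_true(all(is.na(ann$species)))
  expect_false(anyNA(ann$family))
  validate_annotation_table(ann)

  # single-lineage profile: every microbial feature shares it
  prof <- default_taxonomy_profile()[1, ]
  prof$prob <- 1
  ann1 <- generate_annotations(ids[1:50], profile = prof, human_fraction = 0,
                               truncation = c(genus = 0, species = 0),
                               seed = 3)
  expect_true(all(ann1$genus == "Bacteroides"))

  # genus sampling frequencies within binomial 99% bounds
  prof3 <- default_taxonomy_profile()[c(1, 4, 9), ]
  prof3$prob <- c(0.5, 0.3, 0.2)
  ann3 <- generate_annotations(sprintf("g%05d", 1:10000), profile = prof3,
                               human_fraction = 0,
                               truncation = c(phylum = 0, class = 0, order = 0,
                                              family = 0, genus = 0,
                                              species = 0),
                               seed = 4)
  obs <- table(ann3$genus) / nrow(ann3)
  for (k in seq_len(3)) {
    g <- prof3$genus[k]; p <- prof3$prob[k]
    expect_lt(abs(obs[[g]] - p), 2.576 * sqrt(p * (1 - p) / 10000))
  }

  # malformed profile rejected
  bad <- prof3; bad$prob <- c(0.5, 0.3, 0.3)
  expect_error(generate_annotations(ids[1:5], profile = bad, seed = 1),
               "sum to 1")
})

test_that("split_seed is deterministic and collision-free", {
  expect_identical(split_seed(11, 4), split_seed(11, 4))
  expect_false(any(duplicated(split_seed(11, 100))))
  expect_false(identical(split_seed(11, 4), split_seed(12, 4)))
})
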