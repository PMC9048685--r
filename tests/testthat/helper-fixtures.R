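# shared fixtures, built in code

# tiny intensity matrix with known values
toy_matrix <- function() {
  m <- matrix(c(2, 1, 1,
                0, 3, 0,
                5, 0, 4,
                1, 1, 1), nrow = 4, byrow = TRUE)
  dimnames(m) <- list(paste0("s", 1:4), paste0("f", 1:3))
  m
}

# annotation table where every field is chosen by the caller
make_annotation <- function(feature_id, origin = "microbial",
                            superkingdom = NA, phylum = NA, class = NA,
                            order = NA, family = NA, genus = NA,
                            species = NA, function_code = NA) {
  data.frame(feature_id = feature_id, origin = origin,
             superkingdom = superkingdom, phylum = phylum, class = class,
             order = order, family = family, genus = genus,
             species = species, function_code = function_code,
             stringsAsFactors = FALSE)
}

# 50-peptide toy with one 10-member genus, used by the enrichment oracle
enrichment_toy <- function() {
  bg <- sprintf("p%02d", 1:50)
  ann <- make_annotation(bg, superkingdom = "Bacteria", phylum = "Ph",
                         class = "Cl", order = "Or", family = "Fa",
                         genus = rep(c("GenusA", "GenusB"), c(10, 40)))
  list(background = bg, ann = ann)
}

# small seeded two-group cohort with planted always-detected effects
planted_cohort <- function(n_features = 100, n_planted = 5, log2fc = 2,
                           n_per_group = c(15, 15), seed = 101) {
  ref <- default_reference_distribution(n_features, seed = seed)
  planted <- ref$feature_id[seq_len(n_planted)]
  ref$pi[seq_len(n_planted)] <- 1
  cohort <- generate_cohort(ref, n_per_group,
                            effects = effect_spec(planted, log2fc),
                            seed = seed + 1)
  list(cohort = cohort, planted = planted, ref = ref)
}
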