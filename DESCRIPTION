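Package: lumiprot
Title: Statistical Analysis of Colonic Luminal Metaproteomes
Version: 0.1.0
Authors@R: person("Lumiprot", "Developers", email = "lumiprot@example.org",
    role = c("aut", "cre"))
Description: End-to-end statistical analysis of peptide-level metaproteomic
    intensity data from colonic luminal contents of colon cancer patients:
    alpha-diversity profiling with nonparametric group comparisons,
    principal-component partial R-squared (PCPR2) decomposition of the
    variance explained by clinical covariates, sparse partial least squares
    discriminant analysis with repeated-split stability selection,
    permutation-based taxonomic and functional enrichment with a
    covariate-residualized sensitivity analysis, regularized canonical
    correlation between microbial and host peptide blocks, and empirical
    power and sample-size estimation by subsampling from a simulated
    reference population. A seeded synthetic-data generator (zero-inflated
    log-normal intensities, hierarchical taxonomic annotations, clinical
    covariates) provides ground-truth cohorts for testing every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    optparse,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
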