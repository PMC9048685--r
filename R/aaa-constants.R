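# Shared constants (this file loads first).

# the fixed seven-rank NCBI-style ladder used for lineages; intermediate
# clades are unsupported
TAXONOMIC_RANKS <- c("superkingdom", "phylum", "class", "order",
                     "family", "genus", "species")

CLINICAL_COLUMNS <- c("sample_id", "gender", "age", "site", "stage",
                      "grade", "tils")

ENRICHMENT_LEVELS <- c(TAXONOMIC_RANKS, "function")
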