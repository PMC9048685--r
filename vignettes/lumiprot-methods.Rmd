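---
title: "Statistical methods for colonic luminal metaproteomes"
author: "lumiprot developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for colonic luminal metaproteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumiprot)
```

## The data and the problem

lumiprot analyzes label-free shotgun metaproteomic data from colonic luminal
contents of colon cancer patients. The measurement unit is the peptide: each
sample yields tens of thousands of peptide features, each with an MS1
intensity used as an abundance proxy (zero meaning "not detected"), an
origin class (microbial or human), a taxonomic lineage assigned upstream by
lowest-common-ancestor classification (and therefore possibly truncated
below some rank), and an optional functional code (a KEGG orthologous group
`Kxxxxx` or a custom `CKO-` code for proteins sharing a name but lacking a
KOG). Clinical covariates per patient are gender, age, tumor site
(right/left colon), AJCC stage I--IV, grade G1--G3 and the percentage of
tumor-infiltrating lymphocytes (TILs).

The pipeline asks, end to end: how diverse is each sample's peptide
repertoire; how much of the dataset-wide variability is attributable to
each clinical variable; which small peptide panels discriminate clinically
defined groups; which taxa and functions are over-represented in those
panels; how do microbial panels co-vary with host peptides; and how many
patients per group would a differential study need.

## Clinical groupings

Three dichotomizations drive all two-group analyses: stage I--II vs.
III--IV, grade G1--G2 vs. G3, and TILs-positive (>= 5%) vs. TILs-negative
(exactly 0%). TILs values strictly between 0 and 5 are not covered by the
rule; `assign_groups()` rejects them rather than silently binning, because
any assignment would be a silent analytic choice. Rows with missing
clinical fields are rejected at validation, mirroring the exclusion of
cases with incomplete clinicopathological information. On the bundled
24-patient cohort the groupings give 12/12 (stage), 17/7 (grade) and 12/12
(TILs) — these are the worked-example targets of `scripts/acceptance.R`.

## Abundance handling

Peptide intensities are kept as-is; zeros are structural ("not detected"),
not missing. No cross-sample normalization is applied by default because
the upstream quantitation procedure is already aligned across runs;
`total_sum_scale()` is available as an opt-in. The default log transform is
`log2(x + 1)`: base 2 so effect sizes live on the log2 fold-change scale
used by the power module, pseudocount 1 so non-detection maps to 0. Both
are configurable.

Category abundances (a genus, a function) are the sum of the intensities
of all peptides annotated with that category; peptides unannotated at the
requested rank go to an explicit `unassigned` bucket so per-sample totals
are conserved exactly — a property the tests assert to 1e-9 relative
tolerance.

## Alpha diversity

Richness is the count of nonzero-abundance peptides. The Shannon index
uses within-sample relative abundances with zero-abundance terms
contributing 0, which makes samples with different peptide counts
comparable; because the index is scale-invariant, whether intensities are
first normalized per sample is immaterial. The index is returned with the
standard sign, `H = -sum(p_i log p_i) >= 0` in nats. Two groups are
compared with the two-sided Wilcoxon rank-sum test, three or more with
Kruskal--Wallis; the Wilcoxon implementation (from the stats package) uses
the exact null below 50 observations per group in the absence of ties and
the tie-corrected normal approximation otherwise, a deterministic and
therefore reproducible rule. For comparisons by age, which is continuous,
the default grouping is tertiles.

## PCPR2 explained variance

The principal-component partial R-squared procedure has two steps: (1) PCA
on the column-centered (log) intensity matrix; (2) for each clinical
variable and each retained component, the R-squared of the regression of
the component scores on the variable — a one-way ANOVA R-squared for
categorical variables, a simple regression R-squared for continuous ones —
summed with weights proportional to the PCA eigenvalues. All components
with nonzero eigenvalue (up to n - 1) are retained by default and the
weights are normalized over the retained set, so the explained proportion
lies in [0, 1] and is comparable across runs with different component
caps. Each variable is assessed marginally, not partialled against the
others; the jointly-modeled Type-III variant is intentionally out of
scope. Significance, when wanted, comes from `pcpr2_permutation_test()`,
which re-runs the decomposition under shuffles of the variable.

The headline explained-variance percentages reported for the original
deposited cohort (17.6% microbial / 29.8% host) require that cohort's
peptide data and are not reproduction targets; the tests instead pin the
method down with constructed cases — a perfectly confounded binary
variable explains ~1, two orthogonal designs driving two equal-variance
components explain ~0.5 each (a quantity invariant to rotations within the
tied eigenspace), and an independent variable falls below its own
permutation 95th percentile.

## Sparse PLS-DA with stability selection

The discriminant engine is a two-class sparse PLS: the class factor is
expanded to a centered indicator matrix, and per component the X-weight
vector (the leading left singular vector of the X'Y cross-covariance) is
soft-thresholded so exactly `keepX` features survive, followed by
regression deflation of both blocks. With `keepX = p` this reduces to
dense PLS-DA, whose first loading is parallel to the class-mean difference
direction — the reduction the tests verify. Columns are autoscaled to unit
variance by default (the usual PLS convention); without it, the covariance
criterion is dominated by high-variance features, which in zero-inflated
data means the most dropout-prone ones. Ties in the soft-thresholding are
resolved by magnitude then feature index, with magnitudes quantized at 12
significant digits so floating-point near-ties (e.g. duplicated columns)
behave like exact ties.

Class prediction assigns a sample to the nearest class centroid in
component-score space (Euclidean); the continuous decision value for ROC
analysis is the difference of squared centroid distances. Accuracy is the
fraction of correct predictions of the full-data fit; AUC is averaged over
20 stratified 80/20 train/test splits.

Hyperparameters (ncomp, keepX) are tuned once on the full data by
stratified cross-validation minimizing the balanced misclassification
rate, with ties broken toward the smallest keepX then the smallest ncomp;
re-tuning inside every resample is available behind `retune = TRUE` but is
much slower and was not the reading adopted from the single tuning pass
the original procedure describes. Stability selection then refits the
model on many stratified 80% training splits (80/20 matching the AUC
procedure; the original split proportion is unstated) and retains features
selected in at least 50% of resamples.

Two notes on what a green recovery test establishes. First, the recovery
fixture plants effects on *fully detected* features: an injected log-scale
location shift acts on the detected component only, so a dropout-prone
carrier mixes the effect with detection noise and recovery would measure
the detection process more than the selector. Second, under a pure-noise
cohort the *expected* selection frequency of any given feature is
keepX/p, but individual "lucky" features can persist across resamples
(resamples share 80% of the data), so the null check asserts the expected
frequency and the selected-set size relative to the planted alternative,
not a hard cap on the maximum frequency.

## Enrichment with a permutation null

Each selected panel is tested for over-representation of every category at
every rank (and of function codes) against the full peptide background
with a one-sided Fisher exact test. Nested lineages are tested at each
rank separately with no hierarchical pruning, so a genuinely enriched
clade shows up as a cascade across ranks. Because of that hierarchical
dependence and the many categories, inference rests on the permutation
null: category labels are shuffled across the background (sizes preserved
exactly — the standard exchangeable null), the per-category selected-set
count is recomputed, and the empirical p-value is
`(1 + #{permuted >= observed}) / (B + 1)`, floored at `1/(B+1)` (with B =
10,000, the "<0.001" floor). Direction ("higher in" which group) is the
group with the larger mean summed intensity of the category's selected
peptides — an operational definition chosen here, as none is stated in the
field's tables. Categories with fewer than 2 selected peptides are
reported but flagged low-support.

The sensitivity analysis repeats the *entire* procedure — selection and
enrichment — on the residuals of the per-feature regression of log
intensities on the other clinical covariates; rank-deficient covariate
designs drop redundant columns with a warning. A category is flagged
significant when its empirical p-value is below 0.05 in the main and/or
the sensitivity analysis (both flags are emitted, since "and" and
"and/or" readings both appear in practice).

## Regularized CCA

For a microbial peptide cluster against the host peptide block (or vice
versa), canonical directions solve the ridge-regularized eigenproblem
`(Cxx + l1 I)^-1 Cxy (Cyy + l2 I)^-1 Cyx`, computed through the symmetric
inverse-square-root form so correlations are real and clipped to [0, 1].
Regularization makes the problem well-posed with more features than
samples; the penalties default to a leave-one-out grid search maximizing
the held-out first canonical correlation (`tune_rcca()`), as no penalty
value is conventionally fixed. Signs are fixed so the largest-|loading| X
feature is positive, making the extracted clusters reproducible.
Correlated clusters are cut at |loading| >= 0.2 on the first variate,
*after normalizing loadings to the block maximum* so the rule does not
depend on the arbitrary scale of the canonical direction; the cut rule is
a documented stand-in, as no rule is stated for the published cluster
sizes. Each nonempty cluster feeds back into the empirical enrichment.

## Synthetic cohorts

The generator is a per-feature zero-inflated log-normal: detection with
probability `pi_f`, detected intensities `exp(Normal(mu_f, sigma_f))`.
The three parameters are either fitted from any supplied matrix
(`fit_reference_distribution()`, with a sigma floor of 0.1 so constant
features remain generable) or drawn once from documented defaults chosen
to resemble label-free metaproteomic data: `pi ~ Beta(1.2, 1.8)` (most
peptides seen in a minority of samples), `mu ~ Normal(ln 1e6, 2)` (MS1
intensities roughly 1e4--1e8), `sigma ~ 0.3 + Gamma(2, 4)` (log-scale
spread 0.3--1.5). Effects are location shifts of `log2fc * ln 2` on the
detected component in the designated group — an exact log2 fold change of
group geometric means — leaving detection probability unperturbed, the
simplest reading of an injected fold-change effect. Clinical covariates
are drawn independently from the empirical marginals of the bundled
24-patient cohort. Annotations sample full lineages from a configurable
profile (defaults echoing the dominant gut genera: *Bacteroides*,
*Faecalibacterium*, *Clostridium*, *Ruminococcus*, *Bifidobacterium*,
*Escherichia*, *Fusobacterium*, *Methanobrevibacter*, ...) and truncate
bottom-up with per-rank stop probabilities, emulating LCA assignments of
varying depth. One master seed fans out to per-stage substreams through a
documented splitting rule (`split_seed()`), so every output is a pure
function of (inputs, seed).

What the generator does *not* emulate: between-feature correlation,
sample-level sequencing/acquisition depth effects, batch structure, and
any missingness mechanism beyond per-feature Bernoulli detection. A green
test therefore establishes correctness of the statistical machinery under
a known, idealized data-generating process — not performance on real
metaproteomes.

## Power analysis

A reference population of 2 x N individuals is simulated from the
reference distribution with 100 differentially abundant features per log2
fold-change tier {1.25, 1.5, 2} injected in one group (features eligible
to carry an effect must have detection probability >= 0.2). For each
candidate per-group sample size N, patients are repeatedly subsampled
without replacement, every feature is tested with a two-sided Wilcoxon
rank-sum test on log2 intensities (rank-sum matches the pipeline's
nonparametric posture and tolerates zero inflation; a Welch t mode is
provided for comparison), p-values are Benjamini--Hochberg adjusted over
all features at alpha = 0.05, and power for a (N, tier) cell is the mean
per-feature rejection rate of that tier's features. The per-feature test
is vectorized (normal approximation with tie and continuity corrections),
which the tests verify against `stats::wilcox.test` to 1e-10.

The default N grid spans 15--200 per group, covering both of the two
ranges quoted in different parts of the original description (15--100 in
the methods, 30--200 in the results). Desk-scale defaults (2,000 features,
2 x 1,000 individuals, 200 subsamples) keep the suite within minutes; the
full-scale design is a matter of arguments, not code.

A caveat stated openly: under the zero-inflated log-normal world with
effect carriers eligible at `pi >= 0.2`, absolute power accumulates more
slowly than the published curves (which derive from an mRNA-style
simulator over the deposited cohort's feature distribution, with no
comparable dropout). The acceptance checks therefore pin the *qualitative*
surface — FDR calibration under the null, monotonicity in N and in effect
tier (tolerance 0.03 for Monte-Carlo noise), and the tier ordering
N*(2.0) <= N*(1.5) <= N*(1.25) of the 80%-power sample sizes — rather
than the published 30/50/70 thresholds, which are not reachable without
the deposited data.

## Numerical choices and degenerate inputs

* Wilcoxon on fully tied data returns p = 1 (no evidence) instead of NaN.
* PCA eigenvalues below 1e-12 of the maximum are dropped from the PCPR2
  weights; constant clinical variables yield explained = 0 with a warning.
* Empirical p-values always include the +1 continuity correction.
* `soft_threshold_keep` quantizes magnitudes at 12 significant digits and
  falls back to unshrunk weights when a boundary tie would annihilate the
  kept set.
* Clustering with fewer than 2 selected features proceeds on what is
  available, with a warning.
* All Monte-Carlo tolerances in the tests are 3 standard errors of the
  relevant estimator, computed in the test itself.

## Known limitations

Multi-class discrimination is out of scope (all comparisons here are
two-group). The PCPR2 variant is marginal per variable. The CCA is dense,
not sparse, and quadratic in the larger block's feature count. The
synthetic world is independent across features; calibration statements
(e.g. the enrichment false-positive band) are with respect to that world.
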