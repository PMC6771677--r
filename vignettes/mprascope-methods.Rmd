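---
title: "Models and methods behind mprascope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mprascope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

mprascope is an analysis toolkit for massively parallel reporter assays
(MPRA): experiments that clone thousands of candidate regulatory sequences
into barcoded reporter constructs and read out, per construct, the abundance
of transcribed RNA relative to the construct DNA. This vignette documents
the statistical models behind each stage, the tunable parameters and their
defaults, the design decisions that were genuinely open, what the bundled
simulators emulate, and the known limitations.

## Quantifying transcription rate

Per region, each barcode carries a plasmid (DNA) count and an RNA count. We
model DNA counts as Gamma distributed, and RNA counts, given the plasmid
count, as Poisson with mean `alpha * dna * depth`; `alpha` is the
transcription rate and the quantitative MPRA output. Marginalizing the Gamma
plasmid abundance yields a negative-binomial RNA likelihood, which motivates
the estimator in `estimate_alpha()`:

1. **Stage 1** fits the DNA counts by Gamma method of moments. In the model
   implemented here, plasmid copies are observed without extra noise, so the
   fitted latent plasmid count of a barcode is its observed DNA count; the
   stage-1 fit supplies the pooled dispersion default.
2. **Stage 2** maximizes, per region, the negative-binomial likelihood of the
   RNA counts with mean `alpha * dna * depth` and quadratic overdispersion
   `a` (`Var = mu + a mu^2`). `a = 0` is the Poisson limit with closed form
   `sum(rna) / sum(dna * depth)`; for `a > 0` the optimum is found on the log
   scale with `stats::optimize()` (tolerance 1e-10, search window ±8 log
   units around the Poisson estimate). Standard errors come from the
   numerical observed information at the maximum.

Design choices worth recording:

* **Dispersion** is a single per-dataset moment estimate pooled over regions
  (Pearson-type excess residuals), because per-region estimates are unstable
  with ≤ 30 barcodes. A user-supplied non-negative value overrides it.
* **Barcodes with zero DNA** carry no information about `alpha` and are
  excluded from stage 2, with the excluded count reported; a region with no
  informative barcode is returned with `alpha = NA` and a note, never
  silently dropped.
* The two-stage fit deliberately replaces a full nested-GLM treatment of
  covariates (batch, barcode effects): the simulators generate a single
  batch, and the estimator is the minimal one that inverts the stated
  generative model. The count simulator offers an optional multiplicative
  log-normal barcode effect (`barcode_effect_sd`, default off) to probe
  robustness against that simplification.

`call_active()` standardizes `alpha` into a robust z-score against negative
controls (or all regions when no controls exist):
`z = (alpha - median_ref) / (1.4826 * MAD_ref)`. The 1.4826 factor makes the
MAD consistent for a normal scale, which justifies the standard-normal
survival function used for the one-sided p-value; q-values are
Benjamini-Hochberg over all regions and a region is active when
`q < 0.05`. Calling is one-sided (upward deviation): repressed-element
calling is out of scope. `threshold_active()` provides the alternative
categorical rule, `log2(alpha) > 1.5`, used for paired-region comparisons;
a boundary value is inactive.

## Featurization

`featurize_sequences()` computes sequence-intrinsic features: the 1,024
binary 5-mer presence features, the distinct-5-mer count, G/C count, longest
A and T runs, and motif features. Motif scanning (`scan_motifs()`) scores
every position of both strands with the log-odds of the PWM against the
background and computes each score's exact p-value by dynamic programming
over the discretized background score distribution (granularity 0.001 in
log2 units); a hit requires `p < 1e-4`. The motif-density feature is the
maximum number of hit start positions inside any 20-bp window. Zero matrix
cells are floored at 1e-6 at scoring time to keep log-odds finite; a zero
*background* with nonzero matrix weight is rejected instead, because no
finite flooring is defensible there.

Interval features (`overlap_features()`, `locus_features()`) use 0-based
half-open coordinates throughout and define overlap as at least one shared
base. Aggregates are means of member binaries per factor (`tfbs_mean`,
`dnase_mean`, …), optionally restricted to the assay's cell type. The
shuffled-mean control draws, 100 times by default, as many random
non-cell-type TFBS tracks as the cell-restricted aggregate has members, and
averages their mean binaries; `shuffled_mean_control()` turns the same idea
into an empirical p-value for whether cell-restricted tracks beat random
track sets of the same size.

Score-table features (`score_table_features()`) consume pluggable
regions-by-factors tables — stand-ins for external predicted-binding models,
which this package deliberately does not retrain or reimplement — and count,
per region, the factors scoring strictly above their own 90th percentile
across regions ("above" is strict, so constant columns contribute zero).
Expression strata intersect that count with the top / middle / bottom `k`
factors by TPM; the middle stratum takes ranks
`ceiling((m - k)/2) + 1 … + k` of `m` factors sorted descending, a
convention we fixed because only the stratum sizes are standard.

## The nine-test assessment and median ranks

For a quantitative response the seven regression tests are Pearson,
Spearman and Kendall over all regions; the same three restricted to the top
quartile of the response; and Spearman against the quintile index of the
response (empirical quintiles, ties to the lower bin — a determinism choice).
For a binary response the two classification tests are AUROC (rank statistic
with tie correction) and AUPRC (step-wise precision–recall integration,
ties processed as blocks); their significance is a two-sample
Kolmogorov-Smirnov test of the scores of positives versus negatives — the
two-sample form was chosen because no reference distribution is otherwise
defined. With `x = y` the six correlation tests are exactly 1 while the
quintile test is marginally below 1, since binning introduces ties; tests
assert the exact value of its own definition instead.

Features are ranked per test — by absolute statistic for correlations, so a
strongly negative feature is still recognized as predictive, and by raw
AUROC/AUPRC for classification — with average ranks for ties. The
within-dataset rank of a feature is the median of its nine per-test ranks,
and the comprehensive rank is the median of within-dataset ranks across
datasets (features missing from a dataset are excluded from that median).
Robustness is assessed by recomputing the statistics on 100 random 80%
subsamples and reporting mean ± sd.

## Prediction models

The regression ensemble averages four members: an elastic-net linear model
(mixing ratio 0.5 between the L1 and L2 penalties, standardized features),
a random forest, an extremely-randomized-trees forest, and gradient-boosted
trees, each tree-based member with 1,000 estimators. The classification
ensemble averages the class probabilities of random-forest and
extremely-randomized-trees probability forests. Numerical choices:

* The elastic-net penalty strength is not printed anywhere authoritative,
  so we use the smallest lambda of glmnet's default path — a deterministic,
  lightly-regularized choice.
* The gradient-boosted member uses xgboost with
  `max_depth = 3, eta = 0.1, subsample = 1`, the classical
  gradient-boosting configuration.
* Tree members use `min.node.size = 1` (the reference default for these
  ensemble algorithms); all other tree hyperparameters are ranger defaults.
* Member seeds are `spec$seed + member index`, so refits are bit-identical.
* Feature standardization for the elastic net happens inside the training
  fold only; test folds never contribute statistics (no leakage).

Cross-validation (`make_splits()`) deterministically orders region ids with
a locale-independent radix sort and deals them round-robin into 10 sections;
paired datasets sharing regions inherit each other's section assignment so a
shared region is always tested in the same fold on both sides.
`cross_dataset_evaluate()` additionally removes, per fold, every training
row whose region id matches — or whose genomic interval overlaps by ≥ 1 bp,
when intervals are supplied — a test-fold region. Degenerate classification
folds (single-class test labels) are skipped with a diagnostic rather than
failed, so small datasets still evaluate. The shuffle-label null permutes
only the training response.

Both evaluators accept a `folds` argument (default: all ten). Replicated
analyses in the test-suite and acceptance script evaluate one fold per
replicate seed for the expensive within-versus-cross comparison (ten
replicates × two 4-member 1,000-estimator ensembles each) and the full
ten-fold plan for single-run analyses such as hardness; averaging one fold
over ten independent simulations estimates the same quantity as ten folds
of one simulation, at a tenth of the fitting cost.

## Transfer, hardness, and TF overlap

Shared regions of two datasets are categorized by the 2×2 of their activity
labels (`common_active`, `specific_to_a`, `specific_to_b`, `inactive_both`);
either the FDR call or the log2-cutoff rule can supply labels, and both are
reported, since the two rules disagree near the activity boundary. The
hardness of a region is the rank-normalized absolute difference between its
binary label and the cross-dataset classifier's predicted probability,
`(rank - 1) / (n - 1)` with average ranks for ties — invariant to any
strictly increasing transform of the raw errors. Hardness is computed on
test-fold predictions (the only place predictions are defined) pooled over
folds, and category distributions are compared by ECDFs and pairwise
two-sample KS tests.

Predictive TFs are factors whose per-region predicted binding score has a
BH-significant Spearman correlation with activity (`q < 0.05`; high
confidence `q < 0.01`; nonpredictive `q > 0.1`; the sign is kept and the
test two-sided). Pairwise overlap between datasets' predictive sets is
scored by fold enrichment `overlap * N / (|A| |B|)` and an upper-tail
hypergeometric p-value over the universe of TFs scored in both datasets —
the universe choice and the upper tail (an enrichment question) are design
calls recorded here. The expression association test is a
two-sided Wilcoxon rank-sum comparing TPM of the 50 best- versus 50
worst-ranked TFs.

## Variant-effect prediction

Variants are featurized as the difference between the variant and wild-type
sequence features. For this module the k-mer block uses **counts**
(frequencies), not binary presence: a substitution then perturbs exactly the
counts of the ≤ k words it destroys and the ≤ k it creates, which is the
signature the models learn from (presence differencing loses any word that
still occurs elsewhere). Only sequence-intrinsic features enter, because
positional features are constant across variants of the same element;
per-base conservation, or any external predicted score, can be plugged in
through `providers`. The difference of an allele against itself is exactly
zero and differencing is antisymmetric — both are asserted exactly in the
tests. Concatenation of the wild-type and variant vectors is retained behind
`mode = "concat"`.

The discrete (-1/0/+1) model is a ten-member ensemble of five random
forests and five extremely-randomized forests (1,000 trees each,
square-root feature sampling, member seeds `seed + index`), predicting by
highest mean class probability with ties broken toward the lowest class.
Continuous models follow the per-class rosters (promoters: one RF, one ET,
one GB; enhancers: five RF plus five ET) and default to one model per
element, which suits element-specific effect maps; `scope = "per_class"`
is available. `cross_element_evaluate()` fits on all of one element's variants
and tests on all of another's, with the diagonal holding a deterministic
10-fold within-element value.

## What the simulators emulate — and what they do not

* `simulate_counts()`: Gamma plasmid counts (shape 4, scale 25 ≈ 100
  copies/barcode — placeholders, since the dispersion regime of real
  libraries is not published), Poisson RNA given plasmid, log-normal
  two-component activity (inactive spread 0.25 log2 units, the tight spread
  expected of scrambled-sequence controls; active component shifted +2
  log2), 30 barcodes/region, 30% active. No sequencing error, PCR
  jackpotting, or barcode collisions.
* `simulate_sequences()`: i.i.d. background at a stated GC fraction with
  planted motif consensi at recorded positions; uppercase ACGT only.
* `simulate_paired_datasets()`: both datasets observe one feature matrix
  (shared block plus both specific blocks — features are region properties);
  activity of each dataset loads on the shared block and its own specific
  block plus noise. This is the minimal structure producing transferable and
  non-transferable signal; real cross-cell-type structure is richer.
* `simulate_saturation()`: all `3L` substitutions of an element; the
  position-effect map consists of contiguous functional sites
  (`site_length = 8`, coverage `effect_sparsity`) with one effect level per
  site, mirroring the footprint-like sensitive stretches of real saturation
  mutagenesis; a per-alternative deviation (`alt_effect_sd`, default a
  quarter of the site effect sd) and measurement noise are added, and the
  discrete class thresholds the *noiseless* effect so recovery tests have
  unambiguous truth. `site_length = 1` recovers independent per-position
  effects — a substantially harder, arguably unrealistic, target for
  tree learners.

Because all generators are linear-Gaussian or Gamma-Poisson idealizations,
passing tests demonstrate correctness of the machinery and qualitative
reproduction of the transfer/hardness phenomena, not performance on real
MPRA data; none of the published per-dataset performance numbers are
reproducible from synthetic data, and we do not attempt them.

## Problem sizes and runtime

The test-suite and acceptance script run the estimators at the sizes stated
above (500–2,000 regions, 30 barcodes, 10 replicate seeds for calibration
and degradation analyses, saturation elements of 150–300 bp), which we chose
as the smallest sizes at which every property is comfortably away from its
decision boundary. All randomness flows from explicit seeds; no global RNG
state leaks between stages (`with_seed()` restores the caller's stream).

## Known limitations

* No covariate design matrices in quantification (single-batch model).
* The survival function for active calling is standard normal by
  construction of the robust z; heavy-tailed activity under the null will
  inflate calls, which is why control spread matters.
* Motif p-values are exact only up to the 0.001 discretization of scores.
* `overlap_features()` recomputes per-track overlaps densely; thousands of
  tracks × millions of regions would need an indexed implementation.
* Cross-element variant transfer shares only the feature space, not any
  biological prior; with element-specific simulated effect maps it is
  expected (and observed) to be weak.
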