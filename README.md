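# mprascope

Quantification, feature ranking and predictive modelling of massively
parallel reporter assay (MPRA) activity.

MPRA experiments clone thousands of candidate regulatory sequences into
barcoded reporter constructs and measure, per construct, transcribed RNA
relative to construct DNA. mprascope covers the full analysis path for such
experiments, for researchers studying enhancer activity and regulatory
variant effects:

- **Quantification** — per-region transcription rate α from barcode-level
  DNA/RNA counts. DNA counts are modelled as Gamma; RNA counts given the
  plasmid count as Poisson with mean `α · dna · depth`, giving a
  negative-binomial RNA likelihood whose per-region maximum is the estimate
  (`estimate_alpha()`). Active regions deviate upward from negative
  controls on a robust z-score,
  `z = (α − median_ref) / (1.4826 · MAD_ref)`, with one-sided normal
  p-values and Benjamini–Hochberg control at FDR < 0.05 (`call_active()`).
- **Featurization** — 5-mer presence, base composition, PWM motif scanning
  with exact score p-values (dynamic programming over the background score
  distribution, hits at p < 1e-4), binary epigenomic-track overlaps
  (0-based half-open, ≥ 1 shared base) with per-factor means and a
  shuffled-track control, percentile counts over pluggable predicted-binding
  score tables, and locus annotations.
- **Feature assessment** — seven regression tests (Pearson/Spearman/Kendall
  on all regions and on the top activity quartile, plus Spearman against
  activity quintiles) and two classification tests (AUROC, AUPRC) per
  feature; features ranked per test, the within-dataset rank being the
  median of the nine per-test ranks and the comprehensive rank the median
  across datasets; robustness from 100 subsamples of 80% of loci.
- **Prediction** — ensembles averaging elastic net (mixing 0.5), random
  forest, extremely-randomized trees and gradient boosting (1,000
  estimators each) for regression, and the two forests for classification;
  deterministic 10-section cross-validation, consistent across datasets
  sharing regions; cross-dataset transfer with region/interval leakage
  removal; shuffle-label nulls.
- **Transfer hardness** — regions shared by two datasets categorized by
  their activity pattern; hardness = rank-normalized |label − predicted
  probability|, compared across categories by ECDFs and KS tests.
- **TF overlap** — per-dataset predictive TFs (BH-significant Spearman of
  predicted binding vs activity), pairwise hypergeometric overlap
  enrichment, and a Wilcoxon test linking TF predictivity to expression.
- **Variant effects** — saturation-mutagenesis SNV effects predicted from
  variant-minus-wild-type sequence-feature differences, with discrete
  (−1/0/+1) and continuous ensembles and cross-element evaluation.
- **Synthetic data** — generators for every input
  (`simulate_counts()`, `simulate_sequences()`,
  `simulate_paired_datasets()`, `simulate_saturation()`), so the entire
  pipeline runs and is tested without external data.

All user-facing functions take a data frame first and return tibbles, so
stages compose with the pipe; fitted objects support `tidy()`/`glance()`
and results have `autoplot()`/`plot_*()` helpers.

## Worked example

```r
library(mprascope)

sim <- simulate_counts(sim_config(n_regions = 200, n_controls = 50, seed = 42))
activity <- sim$counts |>
  estimate_alpha() |>
  call_active(fdr_threshold = 0.05)
head(activity[c("region_id", "alpha", "log2_alpha", "z", "q", "active")], 4)
#> # A tibble: 4 × 6
#>   region_id    alpha log2_alpha      z      q active
#>   <chr>        <dbl>      <dbl>  <dbl>  <dbl> <lgl>
#> 1 control_0001 0.728    -0.457  -1.53  0.944  FALSE
#> 2 control_0002 1.05      0.0639  0.344 0.713  FALSE
#> 3 control_0003 1.23      0.296   1.42  0.233  FALSE
#> 4 control_0004 1.44      0.524   2.66  0.0157 TRUE
```

Each row is one region: `alpha` is its estimated transcription rate (RNA
per DNA copy), `z` its robust deviation from the negative-control
distribution, and `active` the FDR-controlled call. On this simulation 62
of the 200 test regions are called active (the generator planted 30%
active, and the call is conservative near the boundary), and the estimated
rates track the simulated truth with Spearman 0.995:

```r
sum(activity$active[!activity$is_control])
#> [1] 62
cor(activity$alpha[match(sim$truth$region_id, activity$region_id)],
    sim$truth$alpha_true, method = "spearman")
#> [1] 0.995
```

From here, `featurize_sequences()` + `assemble_feature_matrix()` build the
feature matrix, `test_suite()` |> `within_dataset_rank()` |>
`comprehensive_rank()` rank features, `cross_validate()` /
`cross_dataset_evaluate()` train and evaluate the ensembles, and
`run_pipeline(pipeline_config())` chains every stage on synthetic data in
one call. The vignette (`vignettes/mprascope-methods.Rmd`) documents the
models and every tunable parameter.

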