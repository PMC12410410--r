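# aigps — adaptive individualized gene-pair signatures

Absolute expression values travel badly between transcriptomic cohorts:
platform, normalization and batch differences shift every gene, so a
classifier trained on one cohort's expression scale often collapses on the
next. The *relative* ordering of two genes within one sample is far more
stable. `aigps` builds classifiers from exactly that unit: for each gene pair
*(i, j)* and sample *k* it codes

```
P[l,k] = +1  if  G[i,k] − G[j,k] >  a · sqrt(S_i² + S_j²)
         −1  if  G[j,k] − G[i,k] >  a · sqrt(S_i² + S_j²)
          0  otherwise
```

where `S_i` is gene *i*'s sample standard deviation and `a ≥ 0` is the
**adaptive coefficient**. The threshold `a·sqrt(S_i² + S_j²)` is the scale of
the Welch–Satterthwaite statistic for the within-sample difference of two
genes with unequal variances (degrees of freedom
`ν = (n−1)(S_i²+S_j²)²/(S_i⁴+S_j⁴)`), so `a` is interpretable as a
t-quantile: a pair only counts as *reversed* when the difference is large
relative to the two genes' own variability. `a = 0` reduces to the classic
sign-of-difference (rank) coding.

The pipeline, each stage an exported function:

1. **Screen** (`screen_cohort()`): every pair's ternary codes are tabulated
   against the phenotype classes in a 2×z contingency table (zeros
   excluded); Fisher's exact test (two classes) or Pearson's chi-squared
   test (`N(ΣΣT²/(row·col) − 1)` with `z−1` df, more classes) ranks the
   pairs by p-value, ties broken by canonical pair index
   `l = [Σ_{b<i}(m−b)] + j − i`.
2. **Train** (`train_signature()`): the top-x pairs featurize the training
   cohort (ternary values), a random forest (or KNN/LR/SVM/MLP/XGB/NB) is
   fitted with 3-fold cross-validated hyperparameter selection, and pairs
   with feature importance exactly 0 are pruned before a final refit.
3. **Evaluate** (`predict_cohort()`, `auc()`, `multiclass_metrics()`): AUC
   for binary tasks; macro/weighted precision, recall and F1 for multiclass
   (macro F1 is the harmonic mean of macro precision and macro recall).
4. **Stratify** (`risk_split()`, `km_logrank()`, `cox_hr()`): predicted
   response probabilities become odds `p/(1−p)`; samples above the cohort's
   mean odds form the low-risk group; Kaplan–Meier/log-rank and univariate
   Cox quantify the survival split.
5. **Network** (`build_network()`): signature pairs as directed edges
   (higher mean expression in responders → lower), weighted by forest
   importance.

A built-in generator (`synthetic_spec()`, `generate_cohorts()`) produces
multi-cohort expression data with planted class-reversed pairs,
heterogeneous per-gene noise, batch shifts (global affine, or affine plus
per-gene offsets) and optional exponential survival outcomes, so the whole
pipeline is testable without any external download.

## Worked example

```r
library(aigps)

spec <- synthetic_spec(m = 120, n = 100, k = 8, delta = 3,
                       batch = "nonaffine", survival_hr = 3)
cohorts <- generate_cohorts(spec, n_cohorts = 2, seed = 1)
discovery  <- cohorts[[1]]   # reference cohort
validation <- cohorts[[2]]   # batch-shifted cohort

scr <- screen_cohort(discovery$X, discovery$labels, a = 0)
head(as.data.frame(scr)[, c("rank", "gene_a", "gene_b", "N", "p_value")], 3)
#>   rank gene_a gene_b   N      p_value
#> 1    1  G0002  G0005 100 1.982331e-29
#> 2    2  G0002  G0011 100 1.982331e-29
#> 3    3  G0002  G0012 100 1.982331e-29

sig <- train_signature(discovery$X, discovery$labels, select_top(scr, 30),
                       a = 0, method = "rf", seed = 1, prune = TRUE)
sig
#> aigps_signature: 26 pairs | rf | a = 0 | classes: class1, class2

prob <- predict_cohort(sig, validation$X)
auc(prob[, "class1"], validation$labels)
#> [1] 1

risk <- risk_split(setNames(predict_cohort(sig, discovery$X)[, "class1"],
                            colnames(discovery$X)))
cox_hr(risk, discovery$survival)
#> HR (high vs low risk) = 3.020 [95% CI 1.846-4.939], p = 1.07e-05 (50/50 samples, 77 events)
km_logrank(risk, discovery$survival)$p_value
#> [1] 4.439244e-06
```

The screen finds the planted reversals at vanishing p-values (pairs that
join a planted gene to a background gene whose baseline lies between the two
class means separate equally well and tie with them), pruning trims the
30-pair signature to 26 informative pairs, the signature transfers to the
batch-shifted cohort with AUC 1.0 even though the cohort's scale was tripled
and every gene offset, and the odds-based risk split recovers the planted
hazard ratio of 3.

## Command line

A thin CLI over the same functions lives in `inst/cli/aigps.R`:

```sh
Rscript inst/cli/aigps.R simulate --config sim.yaml
Rscript inst/cli/aigps.R screen   --config run.yaml
Rscript inst/cli/aigps.R train    --config run.yaml
Rscript inst/cli/aigps.R evaluate --config run.yaml
Rscript inst/cli/aigps.R survival --config run.yaml
Rscript inst/cli/aigps.R network  --config run.yaml
```

Configs are strict YAML (see `?read_run_config`); every run writes a
`provenance.json` and is byte-for-byte reproducible from (config, seed).
Exit codes: 0 ok, 1 validation error, 2 runtime error.

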