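---
title: "Adaptive gene-pair signatures: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive gene-pair signatures: model, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(aigps)
```

## The model

Let $G \in \mathbb{R}^{m \times n}$ be an expression matrix of $m$ genes in
$n$ samples. For a gene pair $(i, j)$ the within-sample difference
$G_{i,k} - G_{j,k}$ is, under an approximate-normality working assumption
for the two genes, distributed like a Welch statistic with unequal
variances. Its scale is $\sqrt{S_i^2 + S_j^2}$, where
$S_i^2 = \frac{1}{n-1}\sum_k (G_{i,k} - \bar G_i)^2$ is gene $i$'s sample
variance, and its approximate degrees of freedom are the
Welch–Satterthwaite value

$$\nu = \frac{(n-1)(S_i^2+S_j^2)^2}{S_i^4+S_j^4},$$

which interpolates between $n-1$ (one degenerate gene) and $2(n-1)$ (equal
variances). The package codes every pair and sample ternary:

$$P_{l,k} = \begin{cases}
+1 & G_{i,k} - G_{j,k} > a\sqrt{S_i^2+S_j^2}\\
-1 & G_{j,k} - G_{i,k} > a\sqrt{S_i^2+S_j^2}\\
\phantom{+}0 & \text{otherwise,}
\end{cases}$$

with the canonical 1-based pair index
$l = \left[\sum_{b=1}^{i-1}(m-b)\right] + j - i$, a bijection onto
$1..\binom{m}{2}$ with a closed-form inverse (validated against
enumeration). The **adaptive coefficient** $a \ge 0$ is thus interpretable
as a quantile of $t(\nu)$: a difference only counts as a reversal when it is
large relative to the pair's own variability. Two properties follow
directly and are enforced by tests:

* **Antisymmetry** — coding $(j, i)$ negates the coding of $(i, j)$.
* **Global affine invariance** — for any $c$ and $s > 0$, the coding of
  $sX + c$ (with statistics recomputed) is identical to that of $X$,
  because both the differences and the standard deviations scale by $s$.
  This is the formal basis of the method's robustness to cohort-level
  scale and offset differences. `a = 0` strengthens this to invariance
  under any within-gene monotone ordering-preserving transform of the
  difference sign.

Boundary conventions keep the transform total: the inequality is strict (a
difference exactly equal to the threshold codes 0), and a pair of two
zero-variance genes falls back to strict sign comparison (its $\nu$ is
undefined and `welch_df()` refuses it).

## Variance provenance

$S_i$ is computed by default on the cohort being transformed: every cohort
is coded against its own scale, which is what makes the transform
batch-tolerant without any cross-cohort calibration. For single-sample
deployment, where a cohort SD is unavailable, the trained signature stores
the training cohort's gene SDs and `featurize(..., stats_mode = "frozen")`
reuses them. On an affine-shifted copy of the training cohort the two modes
agree exactly.

A consequence worth understanding: $S_i$ is a *marginal* SD and therefore
includes any between-class separation a gene carries. For a balanced
two-class cohort in which a pair's class-conditional difference means sit at
$\pm\Delta$, the mixture inflates $S_i^2 + S_j^2$ to
$2\bar\sigma^2 + \Delta^2 \cdot (\text{mixing factor})$; algebra shows that
for symmetric balanced mean swaps the threshold $a\sqrt{S_i^2+S_j^2}$
exceeds $\Delta$ for *every* effect size whenever $a \ge \sqrt 2$. In that
regime strongly reversed pairs are coded 0 in most samples and the signal
surfaces only through partial threshold crossings — informative when $n$ is
large (the regime of single-cell discovery sets with thousands of cells),
but sparse at small $n$. This is why the package's small-$n$ synthetic
demonstrations of screening recovery run at $a = 0$ (sign coding), while
larger $a$ remains useful on real data where class structure contributes
only a small share of each gene's marginal variance. The coefficient
defaults follow the intended applications: $a = 2$ for binary
immunotherapy-response-style tasks, $a = 0$ for multiclass tissue
classification, both overridable and tunable.

## Screening

Per pair, the ternary codes are tabulated against the $z$ classes in a
$2 \times z$ contingency table (row 1 counts $+1$, row 2 counts $-1$;
zeros are excluded, so the table total $N$ can be much smaller than $n$).

* $z = 2$: two-sided Fisher's exact test, computed from the hypergeometric
  point probabilities as the sum over tables with the observed margins whose
  probability does not exceed the observed one, with the standard
  $1 + 10^{-7}$ relative guard against floating-point ties. A one-sided
  variant is available by flag. Tests check the implementation against a
  full enumeration oracle built on the factorial identity through `lgamma`,
  and against `stats::fisher.test`.
* $z > 2$: Pearson's chi-squared in the product-moment form
  $N\left(\sum_{ij} T_{ij}^2 / (r_i c_j) - 1\right)$ with $z - 1$ degrees
  of freedom (for a $2 \times z$ table this equals the usual
  $(2-1)(z-1)$), right tail. The form is algebraically identical to
  $\sum (O-E)^2/E$ and tests assert agreement within $10^{-9}$.

Degenerate situations never error mid-scan: an empty table or a zero row or
column marginal yields $p = 1$, parking uninformative pairs at the bottom.
Ranking is by ascending $p$ with ties broken by ascending $l$, so the order
is total and reproducible; it is invariant to sample order and label
renaming. Raw p-values are ranked — selection is by count, not by a
significance cutoff — and an optional Benjamini–Hochberg column is provided
for reporting only. `screen_cohort()` streams pair blocks (default 65,536
pairs, ascending $l$) and retains only each pair's class counts, so memory
stays bounded for large $m$; the blocked result is bit-identical to the
unblocked one.

Note on ranks versus ground truth: when a planted pair separates classes
perfectly at $a = 0$, any pair that joins one planted gene to a background
gene whose baseline lies between the two class means separates perfectly
too, and all of these tie at the minimal $p$. Recovery is therefore best
quantified by p-value (e.g. Bonferroni-level detection), not by absolute
rank.

## Signature training and pruning

Features are the ternary codes themselves. The default discriminative model
is a random forest (`ranger`, impurity importance, single-threaded with a
fixed seed for determinism); KNN, logistic regression, SVM (RBF), naive
Bayes, a single-hidden-layer perceptron and gradient-boosted trees are
available behind the same interface. Hyperparameters are selected by 3-fold
cross-validation over small documented grids (random forest: 100 or 500
trees $\times$ unlimited or depth-8; SVM cost $\{0.1, 1, 10\}$; KNN
$k \in \{3, 5, 11\}$; boosting rounds $\{50, 200\}$), scored by pooled
out-of-fold AUC (binary, first class positive) or accuracy (multiclass),
first grid row winning ties. With ample samples `cv = FALSE` skips
selection and uses the first grid entry. One top-level seed is fanned out
deterministically to fold assignment and every fit; identical inputs and
seed give bit-identical signatures and predictions, which the signature
JSON round-trip (exact serialized payload plus human-readable pair table)
preserves.

Pruning removes pairs whose forest importance is exactly 0 — they were
never used by any tree — and refits with the same seed; if the refit
creates new zeros, one more round is applied (two maximum). Pruning can
only shrink the pair set, and on held-out synthetic data the pruned
signature's AUC stays within a small margin of the unpruned one.

## Evaluation metrics

Binary performance is rank-based AUC (Mann–Whitney, ties counted ½).
Multiclass reports, per class, one-vs-rest precision and recall with the
conservative convention that an undefined ratio (empty denominator) is 0.
Macro precision/recall are unweighted means; **macro F1 is the harmonic
mean of macro precision and macro recall**,
$F1_m = 2 P_m R_m / (P_m + R_m)$ — deliberately *not* the common mean of
per-class F1 scores, which differs (0.7895 vs 0.7333 on the worked
four-sample example in the tests). Weighted variants replace the unweighted
means by class-frequency-weighted ones, with the weighted F1 again the
harmonic mean. Accuracy equals weighted recall whenever every sample
receives a prediction.

## Survival stratification

The trained signature's predicted response probability $p$ becomes odds
$p/(1-p)$; the cohort threshold is the arithmetic mean of the odds, and
samples strictly above it form the **low-risk** group (high response odds
mean longer expected survival), the rest the high-risk group. $p = 1$ gives
infinite odds: such samples are forced low-risk and excluded from the mean,
with a warning. The split always recomputes its threshold from the supplied
probabilities, so rescaled probabilities produce a different cutpoint by
design. Group comparison delegates to the survival package: two-sided
log-rank via `survdiff`, Kaplan–Meier curves via `survfit`, and a
univariate Cox model reporting the high- versus low-risk hazard ratio with
its 95% CI; non-convergence and no-event situations surface as errors, not
silent defaults.

## Gene-pair network

Signature pairs form a directed graph: each edge points from the gene with
the higher mean expression in the positive class to the lower one and
carries the pair's forest importance; vertices carry their degree and
per-class mean expression and are ordered by descending degree so the hub
gene is listed first. Exports: GraphML and a flat edge-list TSV.

## The synthetic generator

`synthetic_spec()` describes a multi-cohort study: $m$ genes with baseline
means uniform on `mu_range` (default 4–10, a log2-microarray-like range)
and noise SDs uniform on `sigma_range` (default 0.5–1.5, deliberately
heterogeneous); $k$ gene-disjoint planted pairs whose class-conditional
means sit at $\mu \pm \delta\bar\sigma$ ($\bar\sigma$ = the pair's pooled
noise SD) and swap between classes — with more than two classes the
reversed class cycles so every class carries signal; and a per-cohort batch
model:

* `"affine"` — a random global $sX + c$ per cohort, which pair coding
  cancels exactly (used to test the invariance).
* `"nonaffine"` — a strong global rescaling (scale 3, offset 10 by
  default, emulating the dynamic-range difference between platforms or
  processing pipelines) plus per-gene offsets with SD 0.75 times each
  gene's noise SD (probe-level effects). The global part alone would be
  invisible to pair coding; the per-gene offsets deliberately break exact
  invariance. The magnitudes were chosen so that the mode fulfils its
  purpose of visibly degrading an absolute-expression classifier — a
  random forest trained on raw expression loses most of its discrimination
  across this shift because its split points no longer overlap the test
  distribution, while pair features lose almost nothing; milder settings
  (e.g. scale 2, offset 6) leave tree ensembles largely intact because any
  per-gene monotone map preserves within-gene ranking and partial range
  overlap is enough for them.

Survival outcomes are exponential with class-dependent hazard (first class
baseline, other classes `hr` times it) and independent censoring drawn as a
competing exponential whose rate is calibrated so the expected censored
fraction equals `censor_rate` exactly; a censoring rate of 1 (or generated
data without events) errors. Everything is reproducible from the master
seed, and each cohort additionally from a seed derived from (seed, cohort
index), so single cohorts can be regenerated in isolation. Ground truth
(planted pairs, batch parameters) is emitted in machine-readable form.

What the generator does *not* emulate: count noise and library-size
normalization, realistic single-cell dropout (a crude zeroing toggle
exists, fidelity is not claimed), gene–gene correlation beyond the planted
pairs, and nonlinear cross-platform warps. Passing tests therefore
demonstrate the pipeline's contracts — calibration, invariances, recovery
under the stated generative model — not performance on any real cohort.

## Numerical and design conventions

* Strict inequalities everywhere a threshold is compared; exact-zero
  importance for pruning; exact string match (after whitespace stripping)
  for gene IDs, with no symbol-alias resolution.
* Shared gene order across cohorts follows the first cohort listed, fixing
  pair indices deterministically; duplicate gene rows are an error, never
  silently collapsed.
* Fisher tie guard $1+10^{-7}$; degenerate-margin conventions as above.
* Pair-block size 65,536 with ascending block order.
* Expression units are metadata; an optional `log_transform` flag applies
  `log2(x + 1)` at load time for linear-scale RNA-seq input, off by
  default since the transform is defined on whatever scale is supplied.
* Labels and survival data are sample-keyed sidecar TSVs, never embedded
  in the matrix file.
* Test problem sizes are kept deliberately modest — up to 300 genes
  (44,850 pairs), 200 samples, five seeds for stochastic properties, 500
  replicates for the survival type-I check — sizes at which every
  stochastic property tested is stable while the full suite runs in well
  under a minute.

## Limitations

The per-pair adaptive threshold uses one global $a$; a per-pair $t(\nu)$
quantile is a possible extension, not implemented. No multiple-testing
control enters selection (by design — selection is by count). Class
imbalance is not rebalanced (resampling schemes were considered and
rejected as out of scope). The marginal-variance inflation discussed above
means that on small balanced cohorts with very strong effects, large $a$
values are conservative; tuning $a$ on validation cohorts via
`tune_coefficient()` is the recommended guard.
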