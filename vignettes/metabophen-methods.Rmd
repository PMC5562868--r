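---
title: "Methods: QC filtering, PLS-LDA discrimination and permutation importance for LC-MS metabolic phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QC filtering, PLS-LDA discrimination and permutation importance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabophen)
```

## Scope and model of the data

`metabophen` analyses aligned untargeted LC-MS feature tables: a samples x
features matrix of peak intensities in which each feature is one aligned
(m/z, retention-time) mass ion, annotated with ionisation mode and
acquisition window, together with sample metadata (genotype, age group,
pooled-QC flag, a clinical colitis score). The motivating design is a
murine colitis study: wild-type and *mdr1a* knockout animals profiled at 6
and 18 weeks of age (group sizes 18/18/17/12), with pooled-QC injections
interleaved through the run. The package implements five connected stages:

1. reliability filtering and normalization of the feature table,
2. genotype discrimination by PLS-LDA with leave-one-out cross-validation
   and full confusion statistics,
3. predictive regression of a clinical score with identity-line
   diagnostics,
4. a feature-permutation importance test based on random-forest
   classification cross-entropy with a 1.96-sigma decision rule and
   Storey q-value correction, and
5. beta-diversity statistics (rarefaction, Bray-Curtis, principal
   coordinates, one-way PERMANOVA) for pathway-abundance count tables.

A synthetic cohort generator reproduces the statistical structure these
stages assume, so the whole pipeline is testable without any external
download.

## Quality-control driven preprocessing

Pooled-QC samples — a mixture of aliquots from every study sample injected
repeatedly — measure purely technical variability: a reliable feature must
reappear consistently in them. The canonical chain is

noise threshold &rarr; singleton removal &rarr; QC reliability &rarr;
correlation filter &rarr; Z-scoring,

and each stage only removes feature columns, never touches sample rows,
and appends a `filter_report` documenting parameters and removed ids.

* **Noise threshold** (default 100 000 intensity units; a stricter
  re-processing pass uses 1 000 000): a feature is kept when its maximum
  intensity over study samples reaches the threshold.
* **Singleton removal**: features detected in exactly one study sample are
  uninterpretable alignment artifacts; "detected" means intensity above a
  configurable floor (default 0). This is the standard metabolomics
  reading of singleton filtering; it can be disabled.
* **QC reliability** (defaults: presence in at least 80% of QCs, peak-area
  RSD at most 30%, retention-time RSD at most 5%): RSD is sd/mean across
  the QC injections, flagged undefined when the QC mean is zero. The RT
  criterion needs per-injection retention times, which exported aligned
  tables usually lack, so it is applied only when an RT observation
  matrix is supplied (the generator emits one); otherwise the report
  records that it was skipped.
* **Correlation filter** (default |r| >= 0.98, Pearson; Spearman behind a
  flag): features are scanned in column order and each retained feature
  removes all later features correlated with it at or above the
  threshold. Keeping the earlier column is a deterministic, order-stable
  convention; `keep = "variance"` keeps the higher-variance member
  instead. Zero-variance columns are treated as uncorrelated with
  everything and retained, with a note in the report.
* **Z-scoring** `(x - mu)/sigma` per feature, the unit-variance scaling
  convention of chemometrics software (weight `1/sd_j`). `mu` and `sigma`
  use study samples only, with the population (n) denominator; QC rows are
  transformed with the same parameters so they remain comparable.
  Whether QCs should enter `mu` and `sigma` is genuinely ambiguous in
  practice; excluding them was chosen because QC rows are near-replicates
  that would shrink `sigma` artificially.
* **Internal-standard ratio**: dividing every feature by an endogenous
  standard (creatine- or histidine-like ion) in the same sample cancels
  per-sample dilution — consequential for urine, where concentration
  varies severalfold between animals.

## PLS-LDA discrimination

The discriminant model regresses the centered one-hot class indicator
matrix on the feature matrix by NIPALS: each latent variable is an
X-weight vector `w` (unit norm), scores `t = Xw`, Y-loadings
`q = Y't/t't`, with both blocks deflated by the rank-one contribution of
`t` before the next component. Five latent variables are the default. A
sample is assigned the class whose predicted indicator response is
maximal, ties broken toward the first factor level — deterministic and
the most common reading of "PLS-LDA"; fitting a linear discriminant on
the latent scores instead is available via `lda_on_scores = TRUE`.

Performance is estimated by leave-one-out cross-validation: the model is
refitted *n* times with one sample held out and the held-out predictions
pooled into per-class one-vs-rest confusion counts, from which recall,
precision, sensitivity, specificity, F-measure, overall accuracy and
Cohen's kappa are derived (kappa from observed versus marginal chance
agreement). Printed-table comparisons round half-up to two decimals.
When features greatly outnumber samples, all features effectively
participate in every training fold, so leave-one-out cannot rule out
over-fitting; the result object carries that caveat.

Two calibration facts shape the tests. First, on label-permuted data
leave-one-out accuracy concentrates slightly *below* 0.5: the held-out
sample's own class is underrepresented in its training fold, a
well-known pessimism of leave-one-out with balanced designs. The
calibration check is therefore one-sided — permuted labels must not
classify better than the binomial chance band — which is the direction
that matters for validity. Second, with strongly separated groups the
procedure must reach accuracy 1.0 exactly, and does.

Score regression (`regress_against_score`) offers PLS1 and random-forest
branches under the same leave-one-out scheme and summarises the
cross-validated predictions by Q² = 1 − PRESS/TSS and the slope and
intercept of predicted versus observed. Scores unrelated to the
metabolome give Q² ≤ 0 and a near-zero slope — the "deviates from the
identity line" diagnostic; a noiseless linear signal is recovered with
Q² near 1 and slope near 1.

## Feature-permutation importance

The importance test asks, feature by feature: does destroying this
feature's association with the class labels measurably degrade the
classifier? Concretely:

1. Fit a random-forest classifier `n_repeats` times (default 100) on the
   unpermuted table with distinct derived seeds; record the mean and
   standard deviation (sigma) of its classification cross-entropy
   `-(1/N) sum log p_hat(true class)` in nats, evaluated on out-of-bag
   predictions.
2. For each feature, permute its column (a fresh permutation per repeat),
   refit, and average the cross-entropy over repeats.
3. Flag the feature significant when `delta = mean_permuted -
   mean_baseline` exceeds `1.96 * sigma`; report the one-sided normal
   p-value `P(Z > delta/sigma)` and Storey q-values.

Out-of-bag evaluation was chosen because it gives an honest error without
sacrificing samples to a held-out split (training-set evaluation is
available behind a flag and is systematically optimistic). Natural-log
cross-entropy is the statistics convention. Fresh permutations per repeat
follow from repeating the permutation loop; a fixed-permutation mode
exists for variance decomposition studies. The forest uses 500 trees and
the default `floor(sqrt(p))` features per split unless overridden;
smaller forests are used in the package's own simulations, where problem
sizes (12 + 12 samples, 300–500 features, 25 repeats) were chosen to make
the full calibration and recovery studies convenient on a single CPU.

Two statistical properties deserve note. The rule compares a *mean* of
`n_repeats` cross-entropies against the *single-repeat* sigma, so under
the null `delta/sigma` has standard deviation near `sqrt(2/n_repeats)`,
far below 1: the realized false-positive rate of the 1.96-sigma flag sits
well below the nominal one-sided 2.5% — the rule is conservative, which
the null-calibration test asserts as an upper bound. Conversely, when
several informative features carry redundant signal, permuting any single
one is partially masked by the others, attenuating delta; the one-sided
p-values still separate informative from null features cleanly, so
recovery is asserted at Storey q < 0.05.

The Storey estimator uses the lambda grid 0.05, 0.10, …, 0.95 with a
cubic smoothing spline (3 effective degrees of freedom) extrapolated to
lambda = 1; with fewer than 100 p-values the smoother is unstable and the
conservative fallback `pi0 = min(1, 2 * mean(p))` is used. Forcing
`pi0 = 1` reproduces Benjamini–Hochberg adjusted p-values exactly, which
the tests verify against an independent step-up oracle.

## Beta diversity of pathway tables

Pathway-abundance count tables (e.g. inferred functional pathways from
16S profiles) are rarefied to a common depth (default: the minimum row
total; undersized samples are dropped and reported), compared by
Bray-Curtis dissimilarity `sum|a-b| / sum(a+b)`, ordinated by classical
principal coordinates (Gower double-centering and eigen-decomposition;
negative eigenvalues are reported rather than silently corrected, and
axes use a deterministic sign convention), and tested by one-way
PERMANOVA: pseudo-F from the between/within partition of squared
dissimilarities, with `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)` under
seeded label permutation, or an exact p by enumerating all labeled group
assignments when the design is small. One-way designs only: location,
age and genotype are tested as separate single factors, matching how such
results are usually reported; no interaction terms.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions the pipeline assumes;
its defaults are the cohort structure stated above (3129 ions over four
acquisition windows — positive/negative mode crossed with m/z 60–200 and
140–1250 — groups 18/18/17/12, 8 pooled-QC injections; the number of QC
injections is not fixed by the motivating design and 8 is this package's
choice). Per feature, log-intensities are Gaussian around a baseline
spanning roughly three orders of magnitude (so the noise threshold is
meaningful), with feature-specific biological scatter (log-sd 0.2–0.5).
The genotype effect is a multiplicative fold-change (default 2) on a
small recorded subset of features; the age effect (default 2) acts on a
much larger subset (default 30% of features), so age dominates the
overall variance as in the motivating data. Every study sample is scaled
by a log-normal dilution factor (CV 0.3), which internal-standard ions
share while being biologically near-constant — making ratio
normalization consequential. Noise ions (default 10% of features) sit
near the noise threshold and are intermittently detected in QCs with
high variability, so QC filtering removes them. QC rows are the
feature-wise mean of the study samples under 5% technical noise. Colitis
scores are 0 for wild-type and 6-week knockouts and uniform on [2, 8] for
18-week knockouts, independent of the metabolome by default — the null
structure in which metabolic variation does not track the score — with a
coupled mode as an option.

What the generator does **not** emulate: chromatographic peak shapes,
isotope patterns, alignment errors, batch drift, heavy-tailed or
structured (correlated-block) biological covariance, and missingness
mechanisms other than QC dropout of noise ions. Passing tests therefore
demonstrate that the statistical machinery behaves correctly under the
assumed generative structure, not that any particular biological dataset
will be as well-behaved.

`generate_pathway_table()` produces compositional counts: log-normal
pathway baselines, per-sample log-normal perturbation, multinomial
sampling at a jittered depth near 10 000, and an optional location shift
`exp(group_shift)` on 20% of pathways in the second sample group. With no
shift the PERMANOVA p-value is uniform over seeds; R² grows monotonically
with the shift.

## Numerical conventions and edge cases

* NIPALS convergence tolerance 1e-12, at most 500 inner iterations;
  component extraction stops early (with a recorded note) when the
  residual rank is exhausted, and requested components are capped at
  `min(n - 1, p)`.
* Response-argmax ties break toward the first factor level; PCA and PCoA
  axes are sign-fixed by making the largest-magnitude loading
  (coordinate) positive.
* Probabilities are floored at 1e-15 before logs; cross-entropy is
  reported in nats.
* Undefined ratios (RSD with zero mean, recall with no positives) are
  `NA`-flagged, never silently zero.
* All randomness flows from explicit seeds through derived seed streams;
  RNG state of the calling session is always restored. Repeated runs of
  any routine with the same seed are bit-identical, which the pipeline's
  manifest replay test exercises end to end.

## Known limitations

Leave-one-out with features ≫ samples remains optimistic for the final
refitted model even when the fold predictions are honest. The permutation
importance test inherits the masking behaviour of refit-based permutation
schemes under redundant signal, and its sigma is a refit-variability
scale, not a sampling-variability scale — its p-values are best read as
ordering evidence within one dataset. The correlation filter's
keep-earliest rule is deterministic but not canonical; results depend on
feature order by construction. PERMANOVA is one-way only.
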