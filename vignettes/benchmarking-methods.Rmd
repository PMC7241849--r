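---
title: "Methods: benchmarking microbiome phenotype prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking microbiome phenotype prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `microvoe`, and what its synthetic-data tests do and do
not establish about real metagenomic data.

## The analysis in one paragraph

Starting from a samples-by-genes relative-abundance matrix and per-sample
metadata, the pipeline (i) clusters co-abundant genes into CAGs with canopy
clustering and summarizes each CAG per sample as the 0.75 quantile of its
member genes, (ii) plans subject-grouped, stratified outer and inner
cross-validation folds per phenotype, (iii) per outer fold filters features
univariately on the training rows, tunes each estimator's hyperparameters by
a three-stage grid search scored by inner cross-validation, fits the chosen
configuration and predicts the held-out fold, (iv) scores the pooled
out-of-fold predictions (R² for age, ROC AUC for binary phenotypes, mean
class accuracy for multiclass) with a bootstrap SD, compares each microbiome
model to a demographics-only baseline, and (v) quantifies how similarly the
different algorithms rank features via pairwise Spearman correlation of
importance-weighted rankings.

## Feature engineering

**Normalization.** Gene counts are divided by gene length and then by the
sample's total length-normalized coverage, so each row is a composition
summing to one. All downstream abundances inherit this closure; feature
subsets are *not* re-closed (values keep their original denominators), so a
CAG's abundance means the same thing whichever feature set a model sees.

**Canopy clustering.** Distance is 1 − Pearson correlation between gene
profiles. Defaults: membership radius 0.1 (r ≥ 0.9), seed-retirement radius
0.4, merge radius 0.1, at most 5 centroid walks stopping when the centroid
moves < 0.005, stop fraction 1. Determinism is imposed by processing seed
candidates in decreasing mean-abundance order with lexicographic
tie-breaking, and defining the centroid as the element-wise mean profile of
members. After merging (closest centroid pair first), every gene joins its
nearest centroid within the membership radius; singleton groups are dropped.
The contract we test is not parameter-level fidelity to any particular
canopy implementation but agreement with an exhaustive threshold-clustering
oracle (connected components of the r ≥ 0.9 gene graph) on planted
two-block instances, which holds in ≥ 95% of seeds.

**Quantile aggregation.** The 0.75 quantile uses linear interpolation
between order statistics (R's type 7: the 0.75 quantile of
{0.1, 0.2, 0.3, 0.4} is 0.325). This convention is declared once and used
everywhere, including for many-to-many pathway membership.

**Univariate filtering** (per training fold only). Each feature is scaled
to unit SD and regressed alone against the target — linear regression for
continuous targets (Wald test in closed form), logistic regression
otherwise; multinomial targets use one-vs-rest fits keeping each feature's
smallest p and largest |coefficient|. Selection: if more than 1,000
features have p < 0.05, the 1,000 largest |scaled coefficient| among them;
otherwise, with more than 1,000 features in total, the 1,000 smallest
p-values; otherwise all features. Zero-variance features are excluded with
a warning. Gene-level models use the stricter Bonferroni rule via
`extract_genes_from_top_cags()`: members of the ten most important CAGs,
kept only if their univariate p falls below 0.05 divided by the number of
candidate genes.

**Class weights.** Classification samples are weighted inversely to their
class frequency, normalized to mean one, so the weighted sample count per
class is equal and the total weight equals n. Engines receive them as
per-sample weights (glmnet, xgboost) or per-class weights (SVM, random
forest); KNN and naive Bayes have no weight mechanism and run unweighted.

## Fold construction

All samples of a subject share an outer fold, and, within each outer
training set, an inner fold — the repeated-measures "personal signature"
can therefore never inflate test performance. For categorical targets,
stratification operates at the subject level on each subject's majority
class (subjects may change breastfeeding or antibiotic status between
samples; grouping is primary, stratification best-effort). Continuous
targets balance subject counts only. Packing is greedy: subjects in
decreasing sample-count order are assigned to the fold with the fewest
subjects of their class, then fewest samples. Ties are broken by per-subject
random priorities drawn from the seed — this is the one place the seed
enters, so a fixed seed gives a fixed plan, different seeds give genuinely
different plans, and the partition depends only on ids, never on row order.

## Estimators and hyperparameter search

Eleven configurations cover eight families. Tuned grids are deliberately
small (they are the package defaults, overridable per run): elastic net
tunes mixing α ∈ {0, 0.5, 1} and λ on a log10 grid; the second elastic net
fixes α = 0.5 and tunes λ only; the first random forest tunes the mtry
fraction; the second uses 1001 trees, per-tree sampling of
round(0.632 · n) rows for regression or the smallest class count per class
for classification, and selects mtry by inner CV over the geometric ladder
round(p · 0.9^k) (deduplicated, capped at 10 rungs — the ladder's "step"
is a design reading, not a uniquely determined rule). The first GBM tunes
tree depth and learning rate; the second fixes depth 1, minimum node size
10 and learning rate 0.1, starts at 1,000 trees and doubles them while the
best validation iteration falls in the last 10% of iterations *and* the
mean loss of that decile improves on the previous decile by ≥ 0.1%
(doubling capped at 16× to bound runtime; the cap is recorded). SVMs tune
cost (and γ for the radial kernel) on log2 grids; KNN tunes k; naive Bayes
tunes the Laplace smoothing constant.

The search itself has three stages, all scored by the task metric averaged
over subject-grouped inner folds:

1. **Coarse grid** — the Cartesian product of each hyperparameter's
   arithmetic sequence lo, lo + stride, …, hi, mapped through its monotone
   transform (identity, 2^x, 10^x) *after* sequence construction, so grid
   order is preserved.
2. **Pseudo-gradient exploration** — whenever the best value of a
   hyperparameter sits on the boundary of its explored range, the range is
   extended one stride in that direction and re-evaluated at the other
   hyperparameters' values taken from the combinations tied for the best
   score; the loop ends when every best value is interior or pinned at an
   explorable limit. "Tied" means equal after rounding scores to six
   decimals, which absorbs floating-point noise without conflating truly
   different scores. Evaluation failures (convergence, memory, degenerate
   fits) shrink the explorable limit of the extended hyperparameter to the
   last successful value and are kept in the trace.
3. **Fine tuning** — per hyperparameter, a grid of n_fine points spanning
   the tied best values if there are several, otherwise spanning from half
   a stride on one side of the best value to the second-best value on the
   other side.

A candidate combination only replaces the incumbent best if the refitted
model produces finite predictions on its training rows (some configurations
can score well under CV yet emit NaN when asked to predict). Every
evaluated combination appears exactly once in the returned trace, and the
reported best is reproducible by re-scoring the trace — properties the test
suite asserts, along with equivalence to exhaustive search (to within one
fine-grid step) on deterministic loss surfaces.

## Evaluation

Headline metrics are computed on the *concatenation of out-of-fold
predictions* across the k outer folds, then bootstrapped (default B = 1,000
resamples of size n; the SD of the resampled metric is the reported
uncertainty). Resamples on which a metric is undefined — a single class
drawn for AUC — are redrawn and counted, keeping B effective resamples.
Before resampling, rows are put in a canonical order so the SD is invariant
to input row order. An alternative reading of the evaluation —
re-scoring some "final combined model" on the entire dataset — is not
implemented, because any such model has seen every sample during training;
pooled out-of-fold evaluation is the non-leaking interpretation.

Batch predictions containing NaN are retried one sample at a time; samples
that still fail are excluded and listed (a single poison sample can
otherwise invalidate a whole fold). Naive Bayes frequently produces NaN
*probabilities* while its class labels remain valid; probability-based
metrics are then reported missing while accuracy-based metrics (and the
inner-CV score, which falls back to label accuracy) still work.

The baseline comparison flags significance when the two ±1-bootstrap-SD
intervals do not overlap — a heuristic matching how such results are
conventionally reported with "±" values, not a formal test; no
multiple-testing control is applied across the model grid.

Multiclass models report mean class accuracy (the unweighted mean of
per-class recall, robust to imbalance) as the headline, with plain accuracy
alongside.

## Concordance

For each (phenotype, data type), every estimator's per-feature importances
— |coefficient| × feature SD for elastic nets, impurity/gain for the tree
families, permutation importance (metric degradation on held-out rows) as
the uniform fallback for SVM / KNN / naive Bayes, which expose no native
importance — are averaged over outer folds, zero-filled on the union
feature universe, normalized to sum one, and compared pairwise by Spearman
rho (average-rank ties). Genes are excluded from concordance comparisons:
each phenotype's gene set is filtered differently, so their rankings are
not comparable across models. The per-fold averaging policy and the
permutation fallback are design decisions recorded in each vector's
provenance; rho is invariant to any strictly monotone rescaling of the
weights, so the choice of importance *scale* matters much less than the
choice of importance *source*.

## The synthetic generator

Each gene block shares a latent Gaussian log-abundance factor with
subject-level random intercepts (SD 0.25 against a block SD of 0.8, giving
realistic repeated-measures correlation) and a heavy-tailed block mean;
gene-level noise is added and rows are closed to sum to one. Closure
removes part of the shared block variance (in the limit of one block
holding all the mass, all of it), so the generator calibrates the gene
noise against the *post-closure* shared variance: it computes each block's
shared variance after a noise-free closure pass, then solves the lognormal
correlation identity for the residual SD that makes the realized
abundance-scale Pearson hit the block's target (`noise_sd`, default 0.05,
is a floor on that residual). Planted effects shift a block's latent factor
by `effect` × latent SD: linearly in standardized age, as a step at the age
midpoint, or as a Gaussian bump whose centers tile the age axis in
effect-list order (successional taxa peaking at different ages) with width
one sixth of the age range — the non-linear structure on which tree
ensembles should beat linear models. For a categorical phenotype the shift
applies to the non-reference class, so an effect of 1 separates classes by
one latent SD (about one log-odds unit per SD of block abundance).
Metadata emulate an infant cohort: 300 subjects by default with 3–7
samples each across 4 cohorts, subject-constant sex/country/delivery,
increasing ages, a breastfeeding probability that declines with age, and a
10% cesarean class.

What the generator does *not* emulate: taxonomic realism, strain-level
variation, sequencing noise and compositional zeros, batch effects, or
correlated phenotypes beyond the breastfeeding–age link. Passing tests
establish the pipeline's statistical machinery (no leakage, calibrated
nulls, recoverable planted signal, honest uncertainty), not that any real
phenotype is predictable from real metagenomes.

## Problem sizes and numerical conventions

The test suite runs the full pipeline at reduced reference conditions
chosen to finish in minutes on one CPU while preserving the design's
structure: null calibration uses 80 subjects × 2–3 samples, 150 genes in
30 blocks, 3 replicate simulations, 5 outer / 3 inner folds, and all eight
estimator families; signal recovery plants 10 of 60 blocks with effect 1.5;
the non-linear comparison plants 8 unimodal blocks of 30 with effect 2.
Because a single draw of 80 subjects can, by chance, correlate a block's
subject intercepts with a subject-constant phenotype, null calibration is
judged on the across-simulation mean AUC against the bootstrap SD — the
per-draw fluctuation is a property of small cohorts, not of the pipeline.

Other conventions: scores tie at 6 decimals in the tuner; bootstrap
resampling is seeded and canonically ordered; per-cell seeds are derived
from the master seed by hashing the cell's identity, so any cell can be
reproduced in isolation and whole runs are byte-identical on disk for
deterministic estimators; zero-variance features are dropped with warnings
wherever Pearson correlation or scaling is undefined; glmnet inputs with a
single column are padded with a zero column (it requires two); KNN's k is
clamped to the training-set size.

## Known limitations

* The two configurations per family differ in their tuned sets and fixed
  settings, not in the underlying implementation (one library per family
  is used); the comparison is therefore of *configurations*, not software
  stacks.
* Permutation importance for SVM/KNN/NB is computed on each outer fold's
  test rows, which is noisier than the native importances it is compared
  with.
* The ±1-SD overlap rule has no formal error rate; deltas near zero should
  be read as "indistinguishable", not "equal".
* Pathway aggregation is supported (many-to-many membership), but the
  default synthetic runs exercise CAG, taxon, demographic and combined
  data types only.
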