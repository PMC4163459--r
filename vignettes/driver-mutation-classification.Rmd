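---
title: "Classifying driver missense mutations with rotation forests and feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying driver missense mutations with rotation forests and feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A tumor genome carries thousands of somatic missense mutations, but only a
small fraction — the *drivers* — confer a selective advantage to the tumor
cell; the rest are neutral *passengers*. Separating the two from protein
sequence and annotation alone is a supervised classification problem: driver
examples come from somatic-mutation catalogs, passenger examples from neutral
polymorphism records, and each mutation is a single residue substitution
(wild-type residue W at a 1-based position, mutant residue M) on a known
protein.

`drimm` implements the full pipeline: four feature-encoder families, two
feature-ranking criteria, incremental feature selection, a rotation-forest
classifier, and repeated stratified cross-validation — plus a synthetic
generator that plants class structure mechanistically so every stage can be
exercised and benchmarked without any external database.

## The feature space

Each mutation is encoded in 126 dimensions by default, concatenating four
families:

* **AARC (15 features).** For each amino-acid property scale $i$,
  $\mathrm{AARC}_i(X) = \mathrm{AARC}_i(W) - \mathrm{AARC}_i(M)$ — the
  property change induced by the substitution. The default scales are 15
  classic physicochemical descriptors from the AAindex collection
  (hydropathy, polarity, volume, isoelectric point, accessible surface area,
  secondary-structure propensities, net charge, molecular weight,
  mutability, flexibility), chosen once as a broad, documented default; any
  list of `property_scale` objects can be swapped in, and the
  AAindex-like TSV format is supported for external tables.

* **SSM (51 features).** The element $(W, M)$ of each substitution scoring
  matrix. Defaults: the ten standard BLOSUM/PAM log-odds matrices plus 41
  property-distance matrices ($-|\Delta\text{property}|$) derived from
  further AAindex scales. What the pipeline's structure depends on is the
  counts (15 and 51), not the identities; the sets are configuration.

* **PSS (31 features).** Sequence-level dipeptide composition. The 2-gram
  encoder counts every ordered pair of consecutive residues over the
  20-letter alphabet (400 components); the sequence is also recoded into a
  reduced 6-letter alphabet (D,E,N,Q | H,R,K | C | S,T,P,A,G | M,I,L,V |
  F,Y,W) and 2-gram counted again (36 components), giving a 436-vector per
  protein. On the training set, each gram column is scored with the DX
  discriminant and the top 30 kept; the 31st feature is the linear
  correlation coefficient (LCC) between a sample's full 436-vector and the
  training mean profile — a "how typical is this composition" summary.
  Two mutations on the same protein share identical PSS features.

* **AF (29 features).** Annotated attributes of the kind curated in protein
  databases: 14 binary presence flags (which may be unavailable for a given
  record) and 15 numeric attributes. Missing binaries impute to 0
  (absence-coded, logged); missing numerics impute to the training median.

Total: $15 + 51 + (30 + 1) + 29 = 126$.

The PSS reducer and the AF medians are the only trainable parts of the
encoding, and both are fitted by `fit_feature_extractor()` on the training
partition only. The reducer records the ids of the samples it saw;
`evaluate_on_holdout()` refuses any test matrix that overlaps them, so
train/test leakage through the sequence features is a hard error rather than
a silent bias.

## Feature ranking and selection

Two rankings are implemented:

* **DX** — a Fisher-style discriminant ratio per feature,
  $(\mu_{pos} - \mu_{neg})^2 / (\sigma^2_{pos} + \sigma^2_{neg})$, with
  sample ($n-1$) variances. Zero denominator with separated means is an
  $+\infty$ sentinel that sorts above all finite scores; ties break by
  original column order.

* **mRMR** — greedy incremental ranking by mutual information: the first
  feature maximizes relevance $I(x; c)$; each next feature maximizes
  relevance minus mean redundancy to the already-selected set (MID, the
  additive default) or relevance over redundancy (MIQ). Continuous features
  are discretized into three bins at mean $\pm$ one standard deviation
  (the convention of the mRMR software lineage; the original tool's
  discretization is not published, so this default is a documented choice,
  not a reproduction). MI uses natural logs internally; rankings are
  invariant to the base.

**Incremental feature selection (IFS)** then evaluates every top-$k$ prefix
of a ranking by repeated stratified cross-validation and picks the smallest
$k$ attaining the maximum mean accuracy (parsimony on ties — consistent with
preferring a handful of features over dozens at indistinguishable accuracy).
An audit hook records every feature set handed to the trainer, and a
property test asserts that only ranking prefixes are ever evaluated.

## The classifier

The rotation forest trains each of its trees on a differently rotated copy
of the data: features are randomly partitioned into groups of 3; for each
group a random nonempty subset of the classes is drawn and a bootstrap of
50% of those instances taken; the principal axes of that slice form the
group's orthonormal rotation block; the blocks assemble into a
block-diagonal rotation, and a CART tree is fitted to the fully rotated
matrix. Defaults are pinned to the algorithm's published ones: 10 trees,
groups of 3, 50% instance removal, all components kept, unpruned base tree
with Gini splitting. The base learner is CART rather than the original
C4.5 — an accepted, documented deviation; the ensemble's published behavior
does not hinge on the base-tree flavor.

Numerical choices worth knowing:

* Principal axes come from `eigen(cov(slice))`, not `prcomp`, so the block
  is always a full $p \times p$ orthonormal basis even when the bootstrap
  slice is rank-deficient; eigenvector signs are fixed deterministically
  (largest-magnitude loading positive) for bit-reproducibility.
* A degenerate slice (fewer than two distinct instances) is resampled once,
  then falls back to an identity block with a warning.
* Prediction averages per-tree leaf distributions; a probability tie goes to
  the driver class (the cost of missing a driver is asymmetric).
* Fitting saves and restores the caller's RNG state: a fit is a pure
  function of its spec seed.

## Evaluation

`cross_validate()` uses stratified folds, pools the per-fold confusion
counts within each repeat, computes precision, recall, accuracy, F-measure
and MCC from the pooled counts, and reports the mean and variance of each
metric *across repeats* (per-fold-metric averaging is the documented
alternative; the variance-across-repeats convention is recorded in the
report metadata). ROC area is the rank-statistic (Mann-Whitney) form on
out-of-fold driver probabilities, ties counted half.

Metric conventions: all metrics are stored as proportions on $[0, 1]$ and
rendered as percentages only at the presentation layer; an undefined
precision or recall (degenerate classifier) is reported as missing, never
as 0; an MCC with a zero denominator is defined as 0.

## The synthetic generator

`simulate_dataset()` emulates a balanced labeled mutation set (the balanced
1:1 design mirrors the kind of training set assembled from somatic-mutation
and polymorphism databases; imbalance is configurable for skewed test-set
emulation). Signal is planted *mechanistically*, through the inputs the
encoders actually read, so passing tests exercise the encoders themselves:

* substitution channel (`aarc`/`ssm`): drivers favor radical substitutions
  (large hydropathy change), passengers conservative ones, with log-weights
  scaled by the effect size;
* sequence channel (`pss`): driver-pool proteins are generated with
  within-group dipeptide enrichment;
* annotation channel (`af`): three numeric features shift their driver mean
  by the effect size (in $\sigma$), three binary features shift their driver
  rate by the effect size on the logit scale; binaries are masked missing at
  a configurable rate (default 0.1).

Defaults (chosen once as a realistic small benchmark): 24 proteins of
80–160 residues, 200 drivers + 200 passengers, channels `aarc`, `ssm`,
`af` informative at effect size 2. With effect size 0 every channel is
class-independent and the pipeline's cross-validated accuracy is
statistically indistinguishable from 0.5 — the null-honesty tests assert
exactly that.

What the generator does **not** emulate: mutation recurrence structure,
realistic domain architecture or conservation gradients, correlated
annotation features, and the extreme class imbalance of real screening
settings. Passing tests therefore demonstrate that the pipeline recovers
planted structure of the stated kind and strength — not field performance
on curated tumor data.

A fast tabular mode (`simulate_feature_matrix()`) bypasses the encoders for
selection/classifier unit tests. In its planted benchmark the effect size
is defined as the *combined* class separation across the informative
features (per-feature shift $e/\sqrt{m}$ for $m$ features): this keeps each
individual feature necessary, so the optimal IFS prefix is informative
about the planted count rather than saturating at one or two features.

## Problem sizes in the test suite

The suite runs the statistical checks at deliberately small scale: 100–400
simulated mutations, 10–30 tabular features, 2–10 CV repeats, 10–100 seeds
per property, chosen so each property is measured with enough replication
to be stable under its stated tolerance while the whole suite stays fast on
one CPU. The acceptance script uses 400 training and 240 test mutations.

## Known limitations

* The default scale/matrix sets are a documented, swappable choice; results
  on real data will depend on the tables chosen.
* PSS features are computed from the wild-type sequence by default
  (`pss_sequence = "mutant"` substitutes the mutant residue first); since
  the two differ by one residue the distinction is minor for long proteins.
* The gram-ranking domain defaults to all 436 columns
  (`gram_domain = "aa400"` restricts to the 20-letter block) and the LCC
  profile to the all-training mean (`lcc_profile = "driver"` for the
  class-conditional variant); both choices are exposed because the
  originating descriptions are ambiguous.
* Wild-type residues that disagree with the sequence are rejected, not
  repaired: silent coordinate or isoform mismatches are treated as data
  errors.
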