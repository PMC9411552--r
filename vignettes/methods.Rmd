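---
title: "Methods: balanced-ensemble gene-function prediction and network validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: balanced-ensemble gene-function prediction and network validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmethpred)
```

## The problem

Only a small set of human genes is known to write methyl marks on RNA
(m6A, m5C and related modifications), yet many more genes are likely to
participate in these pathways as enzymes, complex partners or regulators.
`rmethpred` frames the search as severely imbalanced binary classification:
roughly ninety curated positives (Class 1) against the rest of a
~27,000-gene genome (Class 0), with genes described by sparse one-hot
attribute features (tissue-expression indicators, annotation terms, domain
and pathway memberships) grouped into dataset families.

## The balanced-ensemble model

With a positive:negative ratio near 1:300, a single classifier would learn
the base rate. Instead:

1. **Stratified 80/20 split.** Both classes are split independently;
   `floor` applies on the test side, so 92 positives yield 74 training and
   18 test positives.
2. **Balanced negative blocks.** Training negatives are randomly
   partitioned into disjoint blocks the size of the training-positive set.
   Each block plus all training positives forms one balanced training set;
   one model is trained per set, so each negative is used by at most one
   model. `n mod block_size` genes cannot be placed without reuse; they are
   left out and reported (16 of 21,476 at the study's scale). An exact
   use-once partition is impossible for indivisible counts, so "at most
   once" is the enforced invariant.
3. **Genome-wide averaging.** Every model scores every gene; the ensemble
   prediction is the per-gene mean Class-1 probability. Genes that served
   as a training negative for one block are still scored by all models —
   with hundreds of models the single in-training model moves the mean
   negligibly, and excluding it would make the score definition
   gene-dependent.
4. **High-confidence calls.** The top 1% of the probability distribution,
   with the cutoff at the `ceil(0.01 n)`-th ranked score and *all* ties at
   the cutoff included: a classifier that assigns one probability to
   thousands of genes (naive Bayes does) yields a correspondingly larger
   call set rather than an arbitrary truncation. Consensus calls require
   membership in at least 3 of the 5 model-type ensembles.

## Feature filtering

Two per-training-set screens precede training, both on binary features:

* **zero-fraction**: remove a feature that is zero in strictly more than
  70% of the set (kept iff in-set frequency ≥ 0.3);
* **variance**: remove a feature whose population variance `p(1-p)` is
  below 0.16 (kept iff frequency in `[0.2, 0.8]`; population rather than
  sample variance is what makes the 16% rule coincide with this frequency
  band).

Per set the package keeps features passing **either** screen, then merges
the per-set lists across the ensemble (union); the merged list is frozen
for training, cross-validation and prediction. The union-within-set choice
was a genuinely open design point: requiring *both* screens keeps only
frequencies `[0.3, 0.8]` and silently destroys class signal of moderate
effect size — a feature at rate `p1` in positives and `p0` in negatives
sits near `(p1 + p0)/2` in a balanced set, which for `p1 = 0.4, p0 = 0.05`
is 0.225: inside the variance band, outside the zero-fraction band. Under
intersection the generator's planted world loses nearly all signal and an
all-noise set always comes out empty. `select_features(combine =
"intersection")` preserves the stricter reading for comparison.

## The five classifiers

LR, GNB, SVM, RF and GB are implemented natively on binary feature
matrices (no suitable R implementations of SVM/RF/GB are available in the
target environment):

* **LR** — ridge-penalized logistic regression by IRLS (penalty 1.0 on
  slopes, intercept free). The ridge keeps separable balanced sets
  well-posed.
* **GNB** — Gaussian naive Bayes with variance smoothing (1e-9 of the
  largest feature variance), class priors from the training frequencies.
* **SVM** — kernelized Pegasos subgradient descent (linear or RBF),
  `lambda = 1/(cost × n)`, 10,000 iterations by default; Class-1
  probabilities by Platt scaling fitted on 3-fold out-of-fold decision
  values, after which the machine is refitted on the full set.
* **RF / GB** — a purpose-built CART on binary features (a split *is* a
  feature index: `x = 0` left, `x = 1` right). RF grows bootstrap trees
  with per-node feature subsampling and Gini gain; GB performs
  second-order (Newton) boosting of depth-3 trees on the logistic loss
  with leaf values `-G/(H + 1)` and learning rate 0.1. Feature importances
  accumulate split gain weighted by node size and are normalized per
  model.

Tuning follows the protocol of the original study where stated and
declared defaults where not: SVM by 3-fold grid search over kernel
{linear, RBF} × cost {0.1, 1, 10, 100} × bandwidth {0.001, 0.01, 0.1, 1};
RF by a grid over tree count {100, 200, 500} then a 20-draw randomized
search over feature-subsample fraction, depth, minimum split and leaf
sizes; GB by a grid over learning rate {0.01, 0.1, 0.3} × tree count, then
the same randomized search. Grids are small to keep desk-scale runtime and
are fully configurable; `tune = FALSE` trains at the fixed defaults, which
is how the large synthetic acceptance runs stay inside their compute
budget. All randomness is seeded; identical seeds reproduce identical
hyperparameters, folds and fits.

Performance is estimated by stratified, seeded 10-fold cross-validation
(metrics computed out-of-fold and averaged; AUROC per fold by the midrank
statistic, exact under ties) and reported per model type as ensemble means
± sd. Final evaluation averages each metric over every (model, balanced
test set) pair, pools the full hold-out to estimate the false positive
rate at threshold 0.5 (the canonical threshold for balanced training,
which the study leaves unstated), and reports FDR = FP/(FP+TP) and FPR =
FP/(FP+TN) inside the top-k window.

## Network validation

* **Personalized PageRank.** Scores solve
  `r = alpha Pᵀ r + (1 - alpha) v` with `alpha = 0.85`, `v` uniform over
  the seed genes (no degree weighting), transition probabilities
  proportional to edge weight (`combined_score/1000` by default;
  unweighted available since the original analysis does not state which
  it used), and dangling mass redirected to `v`. Sparse power iteration
  stops when the L1 change drops below 1e-10; non-convergence is an
  error, never a silent truncation.
* **Preranked GSEA.** Seeds are removed from the ranking so enrichment
  measures only novel predictions. The running sum adds
  `|score|^p / (set total)` at members (`p = 1`) and subtracts
  `1/(N - n_set)` at non-members; ES is the signed extremum. The null is
  gene-set permutation — random same-size sets from the ranked universe,
  the only permutation scheme available for a preranked statistic. NES
  divides ES by the mean magnitude of same-sign null scores. The
  empirical p counts permutations whose |ES| reaches the observed |ES|,
  with the +1 correction (floor `1/(n_perm + 1)`); because the signed
  extremum's magnitude is exchangeable across permutations this count is
  exactly uniform for a random gene set, which the test suite verifies by
  KS test, whereas a same-sign count over the full permutation total
  cannot be.
* **Communities.** The induced known-plus-predicted subnetwork is
  partitioned by Louvain modularity optimization (igraph's
  implementation, seeded; resolution 1, combined-score weights — both
  unstated in the original analysis and declared here), with modularity Q
  recomputed independently by the package's own weighted-modularity
  formula. Communities are annotated by hypergeometric over-representation
  of GMT gene sets (upper tail, `P(X ≥ k)`), with Benjamini-Hochberg
  adjustment pooled across all (community × set) tests as a genome-scale
  report would be.

## The synthetic world

The generator emulates the statistical structure the method assumes, at
1/10 genome scale: 3,000 genes, 90 positives (the study's ~0.3%
prevalence), six dataset families totalling 2,000 features of which 50 are
signal features — Bernoulli(`p1 = 0.4`) in positives, Bernoulli(`p0 =
0.05`) otherwise — and an undirected weighted network from a stochastic
block model (one 150-gene block holding all positives, five 570-gene
background blocks, within/between edge probabilities 0.10/0.002,
within-block scores 700–1000, between 400–699). Annotation sets mirror
blocks with 5% label noise. Features are conditionally independent given
class; real one-hot attributes are correlated within families, so a green
recovery test establishes that the pipeline finds planted marginal signal,
not that it reproduces the study's numbers — Table-level values (CV
accuracy 0.875, test AUROC 0.973, NES 1.605) require the real feature
matrix and PPI network and are out of reach by design.

One master seed drives everything; stage-level generators derive their
seeds by fixed offsets, and identical configurations reproduce
byte-identical text artifacts.

A consequence worth stating plainly: in the null world (`p1 = p0`) no
feature passes either screen — background frequency 0.05 lies below every
keep region — and `select_features` raises the error its contract
prescribes. The null acceptance run therefore trains on the unfiltered
feature list; its chance-level hold-out AUROC checks the ensemble and
aggregation machinery, not the filters.

## Numerical choices and degenerate inputs

* Prediction ties are broken lexicographically by gene id everywhere a
  ranking is written, so outputs are reproducible.
* The variance-filter boundary is inclusive (frequency 0.2 is kept), and
  a 1e-12 tolerance guards `k/n` grid points from floating-point error.
* STRING-score retention is inclusive (`>= 400`); duplicate edges keep
  the maximum score; self-loops are dropped with a message.
* Gene identifiers are opaque case-sensitive strings; no alias mapping is
  attempted (the namespace that unified the study's sources is unstated).
* AUROC on single-class truth is `NA` with a warning rather than a silent
  0.5.
* An empty merged feature list, an empty seed∩graph intersection, a
  gene set with fewer than two ranked members, and an edgeless graph for
  modularity are all hard errors.

## Known limitations

* The native SVM is a stochastic subgradient solver: adequate for the
  balanced few-hundred-sample sets it is designed for, not a replacement
  for an exact QP solver at scale.
* Pure-R tree growth is comfortable at desk scale (hundreds of samples,
  thousands of features) but would need compiled code at the study's full
  290-set × 50,176-feature scale with tuning enabled.
* The generator does not model correlated features, family-structured
  effect sizes, or degree-corrected network blocks.
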