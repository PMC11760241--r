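---
title: "Multi-omics phenotype prediction with phenomix: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics phenotype prediction with phenomix: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomix)
```

# The problem

phenomix predicts a phenotype — a binary outcome such as long-term versus
short-term survival, or a quantitative trait — from up to three omics layers
measured on the same cohort: gene, miRNA or protein expression, DNA
methylation, SNP genotypes, and gene-level copy-number states. Alongside the
prediction it asks the question practitioners actually care about: *which
markers drive the prediction?* Both halves — a parallel-branch convolutional
network with gradient-saliency marker ranking, and four classical baselines
with coefficient-based importances — share one preprocessing, splitting and
evaluation harness, so their results are directly comparable.

# Encodings

Each omics layer is encoded independently:

* **Expression-like layers** (gene/miRNA/protein expression, methylation):
  every *sample* (row) is z-scored to mean 0, standard deviation 1, using the
  population standard deviation (divisor *n*). Per-sample rather than
  per-feature normalisation is deliberate — it standardises each profile as a
  whole — and a `axis = "feature"` switch offers the more common per-feature
  variant. Missing values are set to 0 *after* the observed entries are
  z-scored, so an imputed value sits exactly at the per-sample mean. A
  zero-variance row maps to all zeros rather than dividing by zero.
* **SNP genotypes**: one-hot over five channels in the fixed order
  A, T, C, G, missing. Missingness is a channel of its own; genotypes are
  never imputed.
* **Copy-number states**: one-hot over the five states (homozygous deletion,
  single-copy deletion, diploid normal, low- and high-level amplification;
  numeric aliases −2…2), again with no imputation.
* **Methylation** can additionally be restricted to CpG markers present in a
  marker-to-gene annotation (promoter/gene CpGs), via `filter_methylation()`.

The channel orders are fixed by declaration and recorded in every saved model,
so inference always sees the encoding that training saw.

# The multi-branch CNN

One 1-D convolution branch per omics layer, over the feature axis, with the
encoding channels as input channels. Each convolution is followed by a
leaky-ReLU activation and non-overlapping max pooling; the branch closes with
batch normalization. The branch output is *flattened* into the branch
representation; the representations of all branches are concatenated and
passed through fully connected layers, each followed by leaky ReLU and
dropout, into a softmax head (categorical) or a single linear unit
(quantitative). The loss is cross-entropy or mean squared error respectively,
optionally weighted by inverse class frequency for imbalanced cohorts, and is
minimised by Adam with decoupled weight decay on the weight matrices. Early
stopping monitors validation loss and restores the best weights.

Two design points deserve justification:

* **Flatten, not global max pooling.** Closing each branch with a global max
  over ~1000 positions makes the branch representation nearly independent of
  a handful of informative features: the maximum of a thousand noise windows
  dominates the few signal windows, and gradient reaches only the argmax
  position. In development this showed up directly — the same network scored
  about 0.25 lower AUC with a global-max closure than with flattening on the
  reference benchmark. Flattening (after local pooling has reduced the length
  8-fold) keeps position-specific signal and keeps the input-gradient
  saliency sharp. `branch_pooling = "global_max"` remains available.
* **Small but heavily regularised.** Omics cohorts have hundreds of samples
  and thousands of features, a regime where large conv stacks memorise.
  The default is a single convolution (kernel 4, 8 filters), pooling width 8,
  one fully connected layer of 32 units, dropout 0.5 applied both to the
  concatenated representation and after the hidden layer, and weight decay
  1e-2. These defaults were selected on the package's own synthetic
  benchmark by held-out cross-validation; they are a starting point, not a
  claim about any particular real dataset, and every field of `model_spec()`
  is overridable (or searchable, below).

Reproducibility: a single integer seed drives weight initialisation, batch
order and dropout; identical seeds reproduce identical training histories.
The output layer is initialised at a tenth of the He scale so initial logits
are near zero and the first epochs are stable.

# Splits, folds, and evaluation

`split_dataset()` produces a 60/20/20 train/validation/test partition
(largest-remainder rounding, so 100 samples give exactly 60/20/20),
stratified by class for categorical tasks. `make_cv_folds()` deals class
members round-robin across k folds with a running pointer, so fold sizes
differ by at most one both overall and per class. Cross-validated evaluation
(`evaluate_cv()`) retrains in each fold and reports held-out AUC (binary),
accuracy (multi-class) or Pearson correlation (quantitative); inside each
fold the CNN carves a stratified fifth of the training part for early
stopping, so the held-out fold is never touched during fitting.

AUC is computed by the rank (Mann–Whitney) formulation — identical to the
trapezoidal area over thresholds, with average ranks resolving ties
deterministically. The precision-recall curve enumerates every threshold
(step convention; the recall-0 endpoint carries the precision of the highest
threshold).

# Baselines and their importances

Logistic/linear regression with an L2 penalty (ridge; `lambda = 1/(n C)`,
`C = 1` by default) via glmnet; an RBF-kernel SVM with probability outputs
via e1071 (`gamma = 1/(p Var(x))`); a CART decision tree via rpart; and a
500-tree random forest via ranger — all fitted on the concatenation of all
encoded layers into one vector per sample, with layer-qualified column names
(`layer:feature:channel`) giving a bijection between columns and
(layer, feature, channel) triples. Importances: absolute coefficients for
the linear model, impurity importances normalised to sum 1 for trees and
forests. The RBF SVM has no per-feature coefficients, so seeded permutation
importance (10 shuffles per column, mean drop in AUC or correlation, clamped
at zero) stands in; this is a documented divergence from a coefficient-based
reading.

# Hyperparameter search

Three strategies: the pre-set default (`default_config()`), manual
(`model_spec(...)`), and sequential model-based search (`tune()`). The
optimizer encodes the search space onto the unit hypercube (log-scaling
log-uniform dimensions, one-hot-embedding categorical ones), evaluates an
initial Latin-hypercube design (a quarter of the budget, at least 4 points),
then fits a Gaussian-process surrogate (squared-exponential kernel,
lengthscale `0.3 * sqrt(dims)`, nugget 1e-6, standardised objective) and
proposes the candidate maximising expected improvement over 256 uniform
candidates plus 64 perturbations of the incumbent. Failed trials are recorded
as `NA`, excluded from the surrogate, and never become the best. With a fixed
seed the whole trial sequence replays identically. The default space (learning
rate log-uniform 1e-4…1e-2, dropout 0…0.5, filters 8…64, kernel 2…8, fully
connected width 16…128, batch size {16, 32, 64}) ships as an editable YAML
file.

# Saliency and marker reports

`saliency_map()` computes the gradient of the target output with respect to
every input entry, in inference mode (no dropout, running batch-norm
statistics), so maps are deterministic. For categorical tasks the gradient is
taken at the pre-softmax logit of the positive class (the second sorted class
level by default) — logits rather than probabilities avoid saturation where
the softmax gradient vanishes. Per feature, the absolute gradient is maximised
over encoding channels (one-hot layers therefore report per feature, never per
channel) and averaged over samples; a max-over-samples variant is available.
Scores are converted to *dense ranks* — rank 1 is the highest saliency, ties
share a rank, ranks have no gaps. `top_markers()` takes the top k (boundary
ties all included) or a saliency threshold; `map_markers_to_genes()` converts
annotated markers (e.g. CpG islands) to their neighbouring gene, passes
gene-typed markers through, deduplicates genes at their best rank, and reports
everything else unmapped.

# Over-representation analysis

The marker-gene list is tested against GMT gene-set collections with the
one-sided hypergeometric tail: for a universe of size N, a set with K members
in the universe and a query of n genes, the p-value is P(X ≥ overlap) with
X ~ Hypergeometric(N, K, n). Although the upstream literature labels this
step "GSEA", the input here is an unranked significant-marker list, and the
test determined by that input is over-representation; a ranked, running-sum
GSEA variant is deliberately out of scope. P-values are Benjamini–Hochberg
adjusted across sets (the adjustment method is our choice; the source
material names none). The universe should be the set of genes the model could
in principle have flagged — typically all model features mapped to genes —
and is always explicit in the API.

# The synthetic benchmark

`synthetic_spec()` / `generate_synthetic()` draw a cohort with known ground
truth so that every stage — encoding, training, evaluation, saliency,
recovery scoring — is testable offline. Continuous layers are i.i.d. standard
normal with a mean shift of δ (in sd units) planted in the positive class at
randomly chosen features; SNP and CNV layers draw per-feature category
frequencies from a Dirichlet prior shared across classes, and planted
features shift `min(0.15 δ, 0.4)` of probability mass onto the rarest
category in the positive class (always feasible, and an error if a requested
shift is not). Missingness is applied uniformly at a configurable rate
(expression and SNP layers; the five CNV states include no missing category,
so a nonzero CNV missing rate is rejected). The ground-truth manifest lists
the planted feature IDs per layer, and `manifest_check()` scores a marker
report against it (precision/recall at k, ties broken by feature ID so the
denominator is exactly k).

The reference conditions — 300 samples, balanced classes, expression
1000 features with 10 planted at δ = 2, SNP 500/5, CNV 200/5, no
missingness — are the package's standing benchmark; the acceptance tests and
`scripts/acceptance.R` run it at 5-fold cross-validation over five generator
seeds. What passing shows: the pipeline recovers strong, independent, planted
signal. What it does not show: performance under linkage disequilibrium,
correlated copy-number segments, beta-distributed methylation values, batch
effects, or any real cohort's noise structure — none of which the generator
models.

# Numerical choices and degenerate inputs

* Population (divisor n) standard deviation in z-scores; zero-variance rows
  map to zeros.
* Batch-norm epsilon 1e-5, momentum 0.9 on running statistics.
* Adam β₁ = 0.9, β₂ = 0.999, ε = 1e-8; decay applies to weight matrices only.
* Kernels and pool widths larger than a (tiny) branch are clamped rather than
  rejected, so toy problems run.
* AUC ties: average ranks. Dense-rank ties: shared rank, no gaps. Top-k ties
  at the boundary: all included.
* Cross-validation folds whose held-out part is single-class are skipped with
  a warning; the report errors only if every fold is skipped.
* Class labels are ordered by `sort()`; the second level is the positive
  class for AUC and the default saliency target. This is recorded here rather
  than guessed at call time.
* Model archives are JSON at full numeric precision (format version 1);
  loading a truncated file or a future version is an error, not a guess.

# Problem sizes used in the shipped checks

The test-suite and acceptance script run the reference benchmark at n = 300
with 1700 features over three layers, five generator seeds, 5-fold
cross-validation, and reduced training epochs (40 epochs, patience 8) — sizes
chosen so the whole suite completes comfortably on a single CPU while leaving
the planted signal clearly recoverable. The enrichment null calibration uses
1000 simulated queries against 20 sets over a 1000-gene universe; the AUC
oracle comparison uses 100 random fixtures of 200 observations with heavy
ties.

# Known limitations

* No GPU path; the network is plain R linear algebra (BLAS). Cohorts of a
  few hundred samples and a few thousand features train in seconds to
  minutes; hundreds of thousands of features will not.
* Multi-class (>2) phenotypes run structurally (softmax head, accuracy
  metric) but are not tuned.
* The synthetic generator plants independent effects; see above for what it
  does not emulate.
* Permutation importance for the SVM measures marginal, not conditional,
  contribution and inherits the metric's variance at small n.
* No batch-effect correction or probabilistic imputation; inputs are assumed
  to be cohort-homogeneous.
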