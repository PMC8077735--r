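---
title: "Predicting protein carbonylation sites: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein carbonylation sites: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Protein carbonylation is an irreversible oxidative post-translational
modification: reactive oxygen species attack the side chains of lysine
(K), proline (P), arginine (R) and threonine (T) residues and convert
them into carbonyl derivatives. Experimentally mapped carbonylation
sites are scarce, so training data for sequence-based predictors are
extremely imbalanced — typically one verified site per tens to hundreds
of candidate residues. carbonylr implements a complete prediction
workflow built around three ideas: a distance-aware sequence encoding,
a hybrid resampling scheme that meets in the middle between the two
class sizes, and a Rotation Forest ensemble of SVMs.

```{r setup}
library(carbonylr)
```

## The DR encoding

A peptide window `R = R1 R2 ... RL` around a candidate residue is
encoded as a count vector with `20 + 400 * d_max` entries. The first
block counts each of the 20 standard residues. Block `d`
(`1 <= d <= d_max`) counts every ordered residue pair `(i, j)` at
*exact* separation `d`: positions `t` with residue `i` at `t` and `j`
at `t + d`. Pair blocks are indexed row-major in the fixed alphabetical
residue order, so `"AC@1"` is the count of A immediately followed by C.

```{r}
v <- dr_encode("AAC", d_max = 1)
v[v > 0]
```

Two conventions deserve comment:

* **Exact distance per block.** The maximum distance parameter could
  also be read as "pairs up to distance d" per block. The exact-distance
  reading is chosen because each block is indexed by its own distance
  and it yields clean conservation identities — for an X-free window of
  length L, block 0 sums to L and block d sums to `L - d` — which the
  test suite asserts under fuzzing.
* **Unknown residues.** Non-standard letters (B, J, O, U, Z, \*) are
  normalized to `X` at input. An `X` occupies a position but feeds no
  count bin, so sequences with ambiguity codes remain usable; the
  conservation sums then hold as inequalities.

Counts are raw occurrences, not frequencies: the undersampler
normalizes columns later, and keeping integers makes the TSV
round-trip bit-exact.

### Window extraction

The encoding is defined for any window length, so windows at sequence
termini are truncated rather than padded with placeholder letters. The
default half-width is 10 (21-residue interior windows): observed
position-specific enrichment in carbonylation data is concentrated
within roughly six residues upstream of the site, so a 10-residue
flank covers it with margin while keeping the encoding local. The
value is a package choice exposed as a parameter, not an empirical
constant.

## Balancing: SMOTE plus KSU

With `n1` positives and `n0` negatives (`n0 > n1`), the number of
samples moved is

```
N = round(k1 * n0 - k0 * n1),   k0 = k1 = 0.5,
```

rounded half away from zero. Both classes are brought to the common
size `M = n1 + N`: the positive class gains `N` SMOTE synthetics and
the negative class loses `n0 - M` rows. With the default equal weights
M is the midpoint of the two class sizes (up to rounding). The
half-away-from-zero rule matters: one of the four canonical training
sets produces a half-integer (11322.5), and banker's rounding would
disagree with the published size by one.

```{r}
compute_plan(618, 26995)
```

**SMOTE** interpolates: each synthetic row is `X + u * (Y - X)` with
`Y` one of the five nearest minority neighbors of `X` (Euclidean
distance in raw DR space — column normalization belongs to the
undersampler only) and `u ~ U(0, 1)`. Base rows are cycled round-robin
over a shuffled minority ordering, so quotas larger than the minority
size are filled exactly.

**KSU** (K-means similarity-based undersampling) removes redundant
majority rows. The majority class is split into `k = 6` k-means
clusters; within a cluster, columns are normalized by their maxima and
the dissimilarity of rows p and q is the squared Euclidean distance of
the normalized rows scaled by `1/n` (cluster size). Pairs from all
clusters are merged into one list sorted by increasing dissimilarity,
and walking that list, one member of each still-intact pair is deleted
at random until the quota is met. Design choices where the procedure
was genuinely open:

* **Cross-cluster allocation.** Nothing prescribes how removals are
  distributed over clusters, so a single globally sorted pair list is
  used: the most redundant pairs lose a member regardless of cluster.
  A per-cluster removal tally is attached to the result. The `1/n`
  scaling is kept verbatim even though it is monotone within a
  cluster; across clusters it mildly favors removals from small
  clusters.
* **Initialization.** k-means uses k-means++ seeding with 10 restarts
  (best total within-cluster sum of squares wins), seeded through the
  R RNG for reproducibility. Only `k = 6` is prescribed; the rest is a
  package choice.
* **Exhaustion fallback.** If the sorted pair list runs out before the
  quota (possible with many singleton clusters), the remainder is
  removed uniformly at random with a warning.
* **Ties.** Equal dissimilarities are ordered by cluster index, then
  pair index, making runs bit-reproducible under a fixed seed.

`smote_ksu()` glues the two together and tags every output row as
`original_pos`, `synthetic` or `original_neg`, so synthetic rows can
never silently leak into an evaluation set.

## Rotation Forest with SVM subclassifiers

Each of `L = 5` subclassifiers is built as follows: the feature
indices are randomly partitioned into `K` subsets (sizes differing by
at most one); for each subset, a bootstrap draw of 75% of the rows
(with replacement — "randomly and repeatedly") restricted to the
subset's columns is analyzed by PCA; the retained loading vectors
(eigenvalue above a small tolerance, default 1e-8) form that subset's
coefficient block. The blocks are assembled into a sparse rotation
matrix whose rows are re-ordered to the original feature order, and an
RBF SVM is trained on `X %*% R` against the full label vector. At
prediction time each sample is rotated by each subclassifier's own
matrix and the positive-class credibility is the mean of the L
probabilities; the decision threshold is 0.5, with the boundary going
to the positive class.

Numerical and design notes:

* **Probability calibration.** libsvm's built-in probability machinery
  shuffles an internal cross-validation with an unseeded C RNG, which
  makes repeated fits on identical data disagree. carbonylr therefore
  fits Platt's sigmoid itself — a two-parameter logistic on the
  training decision values with prior-smoothed targets, optimized by
  BFGS — which is deterministic, seedable, and reproduces the same
  calibration idea. Decision-value orientation is normalized
  empirically (positive class on the positive side) before fitting.
* **SVM hyperparameters** are not prescribed: defaults are RBF kernel,
  `C = 1`, and `gamma = 1 / (n_features * mean feature variance)`, the
  variance-scaled analogue of the common `1/n_features` heuristic.
  Total variance is invariant under the orthonormal rotations, so
  rotated and unrotated fits see the same bandwidth. All three are
  configurable.
* **Degenerate subsets.** When K approaches the feature count the
  subsets hold one to three features each; PCA is still run, and a
  subset whose bootstrap draw is constant falls back to an identity
  block (with a message) rather than aborting the ensemble.
* **PCA components** are loadings only, not scaled by eigenvalues, and
  components with eigenvalue at or below the tolerance are dropped, so
  a subset can contribute fewer columns than features.

A useful consequence of the construction, exploited by the test suite:
with `K = 1`, `L = 1` and a full-rank PCA the rotation is orthogonal,
the RBF kernel matrix is unchanged, and the ensemble reduces exactly
to the base SVM.

## Evaluation metrics

Sensitivity, specificity and accuracy are computed in their error-rate
forms (`Sn = 1 - fn/N+`, etc.), G-mean as `sqrt(Sn * Sp)`. MCC uses
the ratio form with numerator `1 - (fn/N+ + fp/N-)`, which is
algebraically identical to the standard four-product MCC; a published
variant of the ratio form carries the *accuracy* numerator
`1 - (fn + fp)/(N+ + N-)` instead, which is not a valid MCC (on the
worked confusion example `N+ = 10, N- = 100, fn = 2, fp = 10` it gives
0.6924 where MCC is 0.5440). That variant is treated as a typo but kept
reproducible behind `strict_eq13 = TRUE`. When a denominator factor is
zero, MCC is reported as `NaN` with the other metrics intact.

The AUC is the pairwise comparison statistic
`sum u(f_i+, f_j-) / (N+ * N-)` with `u` the strict indicator — ties
contribute 0. This is deliberately kept as the default for fidelity to
the definition above; `tie_correction = TRUE` scores ties as 0.5 and
recovers the conventional Mann–Whitney AUC. Internally the rank-sum
identity with exact tie accounting is used, so both modes are exact at
any size.

## Cross-validation and model selection

`cross_validate()` scans a grid over `d_max` (1–3) and the subset
count `K` (default 300–400 in steps of 10), with seeded stratified
tenfold splits. The selection metric is mean MCC — the primary metric
throughout this literature — with ties broken by AUC, then smaller K.
Cells whose K exceeds the encoding dimension are skipped with a notice
rather than failing the run.

Resampling happens **inside** each training fold by default
(`resample_mode = "per_fold"`): balancing before the split would let
SMOTE synthetics sit arbitrarily close to held-out originals and
inflate every metric. A `global` mode that balances first is provided
for comparability with protocols that report cross-validation on
pre-balanced data; it warns about the leakage. Training folds that are
already balanced (common in synthetic smoke tests) skip resampling
with a message instead of erroring.

## The synthetic generator

`generate_dataset()` emulates the positional signal this classifier
family assumes: proteins drawn residue-wise from a background
distribution (uniform by default; a natural-abundance preset is
included), candidate residues planted on a 21-residue grid so windows
never overlap a foreign motif, and, for positive sites, upstream
positions overwritten with the enriched letter with probability
`theta`. The enrichment geometry follows the observed per-residue
logos: K sites are enriched for K at positions −6…−1, R sites at
−5…−1, T sites at −3…−2, and P sites carry no positional motif (their
default `theta` is 0; K/R default to 0.8 and T to 0.5).

What the generator deliberately does **not** model: homology between
proteins (redundancy filtering is an upstream concern for real data —
use CD-HIT or similar before training), downstream as well as upstream
enrichment, correlations between sites on one protein, and
composition differences beyond the planted motif. Passing the
end-to-end tests therefore demonstrates that the pipeline recovers a
planted positional signal at realistic imbalance (1:5 in the tests)
and stays at chance on null data — not that it attains any particular
accuracy on real carbonylation assays.

`generate_feature_blobs()` is the sequence-free counterpart for
exercising the resampler and ensemble directly: two unit-variance
Gaussian classes separated on 5 informative coordinates out of
(by default) 420.

## Problem sizes used by the test suite

Unit tests run on deliberately small instances (tens of rows, up to
six features) with brute-force oracles. The end-to-end checks use 600
positive and 3000 negative windows with tenfold cross-validation at
`d_max = 1`, `K = 20`, `L = 5` — large enough that SMOTE, KSU,
rotation and calibration all operate at realistic imbalance, small
enough to run routinely; the ensemble check uses 200-sample,
420-dimensional blobs over five seeds. The full published grid
(K up to 400 at `d_max = 3` on tens of thousands of windows) is
reachable with the same functions and a larger machine; nothing in the
implementation is specific to the reduced sizes.

## Known limitations

* KSU materializes each cluster's pair list (`O(m^2)` per cluster of
  size m). At the size of real negative training sets (tens of
  thousands of rows) this is memory-hungry; a blocked or approximate
  nearest-pair search would be the natural extension.
* Platt calibration is fit on the training decision values rather than
  on an internal cross-validation, which can make probabilities
  slightly overconfident on separable data; ranking (and hence AUC) is
  unaffected.
* The SVM grid (kernel, C, gamma) is not searched by
  `cross_validate()`; only `d_max` and K are, matching the workflow
  this package reproduces.
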