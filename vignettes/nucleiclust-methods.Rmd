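---
title: "Nuclear cluster analysis of H&E patches: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear cluster analysis of H&E patches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleiclust)
```

# The problem

Prostate adenocarcinoma is graded by the architectural organisation of the
tissue, not by the morphology of individual nuclei: as grade progresses
from 3 to 5, glands disorganise and nuclei pack into progressively more
numerous and denser communities. `nucleiclust` quantifies that community
structure directly. From an H&E patch it segments the hematoxylin-dark
nuclei, builds the Euclidean minimum spanning tree (MST) over their
centroids, cuts "inconsistent" (long) edges to obtain nuclear clusters,
summarises the cluster geometry in a fixed 26-number descriptor, selects
informative features by majority voting across seven selectors, and
classifies grade either supervised (a stacking ensemble) or unsupervised
(k-medoids).

# Stain model

## Colour transfer

Patches are first colour-normalised against a reference patch in CIE LAB
(sRGB, D65 white point — recorded in the `stain_stats` attribute). The
per-channel map is

$$x' = (x - \bar x_{src})\frac{\hat x_{tar}}{\hat x_{src}} +
  \frac{x + \bar x_{tar}}{2},$$

with channel mean $\bar x$ and standard deviation $\hat x$. The second
term deliberately averages the *pixel value* with the reference mean
rather than adding the reference mean alone (the classical Reinhard
recentring). Two consequences users should know:

* normalising an image against its own statistics is **not** the identity
  map — the output mean moves to $\tfrac{3}{2}\bar x$;
* the output channel mean is $(\bar x_{src} + \bar x_{tar})/2$, which the
  tests verify analytically.

Out-of-gamut values after the inverse LAB transform are clipped, not
rescaled, preserving the printed arithmetic.

## Optical density and deconvolution

Stain concentrations combine additively in optical density,
$OD = -\log_{10}(I/255)$. The literature often leaves the log base
unstated; base 10 is the optical-density convention and, because the
reconstruction $I_c = 255\cdot 10^{-c\,M_c}$ uses the same base,
concentrations are unit-consistent and the
`rgb -> od -> deconvolve -> reconstruct` round trip closes to within one
gray level for any pixel on the stain plane (verified for 10^4 random
pixels). Intensities are clamped to $\ge 1$ before the log so black
pixels map to the finite maximum OD $-\log_{10}(1/255) \approx 2.407$.

"Dividing" a 3-vector of ODs by the $2\times 3$ stain matrix

$$M = \begin{pmatrix} 0.587 & 0.754 & 0.294\\
                      0.136 & 0.833 & 0.536 \end{pmatrix}
  \quad\text{(rows: hematoxylin, eosin)}$$

is realised as the least-squares projection onto the two stain vectors —
the only well-defined reading for a non-square matrix and the standard
practice in colour deconvolution. Off-plane pixels can yield slightly
negative concentrations; these are clipped to zero at reconstruction
(physical non-negativity). The matrix is a configurable constant;
estimating it from slides is out of scope.

# Nuclei segmentation

The hematoxylin-stain image (reconstructed from the H concentration map)
is converted to HSI and its saturation channel — where chromatin is the
most saturated structure — drives the segmentation:

| stage | default | note |
|---|---|---|
| contrast stretch | 1st–99th percentile | linear, clipped |
| threshold | Otsu | parameter-free global method |
| marker separation | 7 px | minimum distance between watershed seeds |
| minimum object area | 30 px | applied before *and* after the watershed |
| structuring element | disc, r = 2 px | per-object closing then opening |

Watershed markers are local maxima of the exact Euclidean distance
transform; flooding the negated distance transform from those markers,
restricted to the foreground, assigns every foreground pixel exactly one
label and splits touching nuclei. All pixel-level primitives (distance
transform, priority-flood watershed, component labelling, morphology)
are compiled code under `src/` because no image-processing package is
assumed. Coordinates are (row, col), 0-based, at pixel centers.

None of these stage parameters is prescribed by the method description
the package implements; each is therefore explicit configuration
(`segment_config()`) with the defaults above, chosen as the standard
values a practitioner would start from.

# MST cluster analysis

The MST over nucleus centroids is grown with Prim's algorithm on the
complete Euclidean graph. MSTs are unique in total weight but not in edge
set under ties, so ties are broken deterministically by the smallest
vertex index. Cutting modes:

* **threshold** (default, 10 px): remove every edge longer than the
  threshold — the working rule of the pipeline;
* **top-k**: remove the k largest edges (ties again by vertex index), so
  a connected tree always yields exactly k + 1 clusters.

Per-cluster summaries are the pairwise member distances
(min/max/total/mean), the intra-cluster MST edge weights
(min/max/total), and the cluster area. Between clusters, positions are
the member means, and both the pairwise centroid distances and the MST
over centroids are summarised. Conventions for degenerate cases, chosen
so the 26-feature vector is always complete and finite:

* singleton clusters report 0 for every distance and area;
* a lone cluster reports 0 for all nine inter-cluster features;
* cluster "area" defaults to the convex-hull area of member centroids
  (0 for fewer than three non-collinear members); summing member nucleus
  pixel areas is available via `area_mode = "nucleus"`. The hull reading
  was chosen because it measures the spatial footprint of the community
  rather than the stained mass, but neither reading is canonical.
* the inter-cluster MST connects cluster *centroids*; linking nearest
  member pairs is a conceivable variant that is not implemented.

# The 26-feature descriptor

`feature_names("both")` maps each descriptive name to its column. The
aggregation grammar is per-cluster-then-aggregate: "total X" is the sum
over clusters of the per-cluster quantity X, "average X" its mean —
the only reading under which the total/average name pairs are mutually
consistent (`total = n_clusters x average`, which the tests assert),
e.g. *total intra-cluster nucleus to nucleus maximum distance* is the
sum over clusters of each cluster's maximum pairwise member distance.
All 26 features are invariant under rigid motions; distances scale
linearly and areas quadratically under scaling.

# Feature selection by majority voting

Seven selectors vote: four filters (Chi-Square, Fisher Score,
Information Gain, ANOVA F) and three wrappers (RFE, permutation
importance, Boruta). How each method was binarised into votes is not
prescribed, so the package uses: score-based methods (filters, RFE,
permutation importance) mark their top `k_select = 16` features —
matching the cardinality of the final published selection — while Boruta
confirms features by its own statistics regardless of k. A feature is
selected with at least `min_votes = 4` of 7 votes.

Method details and their rationale:

* Chi-Square requires non-negative input; features are min-max scaled to
  [0, 1] first and per-class sums are treated as observed frequencies.
* Information Gain is mutual information with features discretised into
  10 equal-width bins — a deliberately simple estimator; a k-NN
  estimator would be the main alternative.
* RFE and permutation importance use the package's random forest
  (impurity importance; 120 trees; fixed derived seeds).
* Boruta compares each feature's importance against the best of the
  shadow (permuted) features over 30 iterations and confirms by a
  one-sided binomial test at alpha = 0.01; tentative features count as
  not selected.

The per-method votes depend on data the package cannot ship, so the
published 26 x 7 vote table is included as a plain-text fixture
(`reference_vote_matrix()`) and the voting arithmetic — 16 selected, 10
rejected at `min_votes = 4`, every per-row count — is validated against
it exactly.

# Classification

Features are z-scored (population SD; a quantity labelled "Var" in the
source formula but defined as sigma — implemented as standard deviation),
with parameters fitted on training data only; zero-variance columns map
to 0.

**Supervised.** A two-level stacking ensemble: base learners k-NN,
random forest, gradient boosting and a regularised second-order
(XGBoost-style) booster; meta learner logistic regression. Five
algorithms, four base slots: logistic regression is the conventional
smooth meta learner, so it sits on top. Meta features are out-of-fold
predicted class *probabilities* (5 inner stratified folds), giving a
`4 x n_classes` meta matrix — probabilities rather than hard labels
because they preserve base-learner confidence. No tree package is
assumed: the CART core and both boosters are implemented in the package
(vectorised split search; Gini for classification, second-order gain
with L2 leaf penalty for the regularised flavour). Base-learner
hyper-parameters are undocumented in the source method and are exposed
as arguments with fixed sensible defaults (150 trees, 80 boosting rounds
at depth 2, shrinkage 0.1, k = 5 neighbours).

**Unsupervised.** k-medoids (PAM: greedy BUILD then cost-reducing SWAP,
Euclidean dissimilarity, medoids constrained to data rows), with
k = number of grade groups. Cluster labels are matched to grades by the
accuracy-maximal one-to-one mapping over label permutations — needed to
score an unsupervised partition against grade labels at all.

**Protocol.** The five-fold scheme evaluates an 80/20 stratified split:
the model is trained once on the 80 %, and the 20 % test set is divided
into five disjoint stratified splits scored separately, plus an
"Average Split" row. Splitting the *test* set five ways (rather than
cross-validating) is unusual but is what the evaluated protocol states;
conventional CV is available via `scheme = "cv"`. Metrics are accuracy,
precision, recall and F1 in percent; with two classes they refer to the
positive class (first level), with more they are macro-averaged
one-vs-rest — the natural reading of a single precision number for three
balanced classes. Zero-denominator precision/recall is reported as 0 and
counted in `n_undefined` rather than silently dropped.

# The synthetic world

Real H&E data cannot ship with the package, so `generate_patch()`
renders patches *through the package's own stain model*: nuclei are
ellipses of hematoxylin concentration ~0.9 (OD units along the printed H
vector, varied ±15 % per nucleus), the background is weak eosin
(concentration 0.25), pixel noise is Gaussian (sigma = 3 gray levels), and
patches are 512 x 512 px — the pipeline's working patch size. Grade
presets emulate the qualitative architecture shift (grade 3: 5 loose
clusters of 8; grade 4: 8 x 10; grade 5: 12 dense clusters of 10 smaller
nuclei). These presets are documentation of the synthetic world, not
claims about real tissue.

Two calibrations make the generator's ground truth *provably* recoverable
rather than recoverable by seed luck:

* member offsets around a cluster center are Gaussian truncated at
  2 x spread, bounding each cluster's footprint;
* cluster centers keep a minimum separation of 7 x spread, so members of
  different clusters are always farther apart than the 3 x spread cut
  threshold used in the recovery tests.

A feature-table generator (`generate_feature_table()`) draws per-class
Gaussians on the scale of the 26 features; "separation s" shifts the
class means of every other feature by s within-class SDs between
adjacent grades, so s = 3 is a strongly separable world and s = 0 is
exact exchangeability (chance-level world). What a green test
establishes is therefore: the pipeline recovers structure *that its own
model family generates*. It does not establish robustness to the things
real tissue adds — out-of-focus regions, stain variability beyond the
linear model, overlapping chromatin textures, gland/lumen structures —
and the published real-data accuracies are not reproduced here.

# Numerical choices and edge cases

* Otsu threshold: between-class variance maximised over the 256 integer
  levels, lowest level on ties; constant images yield an empty mask with
  a warning.
* Contrast stretch of a constant image returns the input unchanged.
* Distance-transform markers: strongest peak first, greedy suppression
  below the minimum separation, raster order on ties — fully
  deterministic, as is the priority-flood watershed (FIFO on altitude
  ties).
* Prim and top-k cutting break ties by the smallest vertex index.
* Convex-hull area uses the shoelace formula over `grDevices::chull`;
  degenerate hulls give 0.
* All stochastic learners consume seeds derived deterministically from a
  single master seed (kept below 2^31).

# Known limitations

* Segmentation is classical (threshold + watershed); heavily overlapping
  nuclei that share a distance-transform peak merge into one label.
* The stain matrix is fixed; slides stained far from the assumed vectors
  will deconvolve poorly.
* PAM is exact but O(n^2) in memory through the dissimilarity matrix;
  for the package's patch-level tables (hundreds of rows) this is
  irrelevant.
* The vote table of the seven selectors on the original cohort cannot be
  re-derived without that cohort; only the voting arithmetic is
  checkable, and is.
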