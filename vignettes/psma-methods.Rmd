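---
title: "Methods behind psma: from similarity matrices to posterior activity surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind psma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psma)
```

# The model

`psma` treats a set of M molecules as a metric space: each molecule is
described solely by its distances to all the others. The deliverable is a
2D map in which every coordinate carries a posterior probability of
activity, obtained in five stages: a similarity-to-distance transform, a
distance-preserving 2D projection, two class-conditional kernel density
maps, a Bayes quotient, and a linear out-of-sample embedding. Each stage is
an ordinary, well-understood technique; the value is in the disciplined
composition, and this vignette records the assumptions and the decisions
taken where the design was genuinely open.

## Similarity to distance

All transforms require normalized similarities, s ∈ [0, 1] with s(x, x) = 1,
and map s = 1 to distance 0 monotonically. The default convex transform

$$d(x,y) = 1 - \frac{k\,s(x,y)}{1 + k - s(x,y)}$$

has one parameter, k > 0 (unitless), defaulting to 0.382 (≈ the Golden
Ratio minus one, a value in the 0.3–0.5 band that gives moderate
convexity). Small k inflates distances among highly similar molecules —
exactly the regime where activity conservation is decided — while large k
degenerates toward d = 1 − s (asserted as a property test at k = 10⁶).
`one_minus`, `inverse` (the pair s = 1/(1+d) ⟺ d = 1/s − 1) and `neglog`
are provided for comparison; for the latter two, s = 0 implies infinite
distance, so similarities are floored at `clamp_sim` (default 10⁻⁶).
Tying the clamp to a floor *similarity* rather than a ceiling *distance*
keeps the maximum distance on each transform's own scale.

The transforms do not guarantee the triangle inequality.
`metric_diagnostics()` quantifies violations (exhaustively for M ≤ 60,
sampled otherwise) and nothing ever "repairs" them: the projections consume
the distances exactly as produced, non-metricity included. This is a
deliberate stance — fixing the metric would change the data the maps are
supposed to represent.

`distance_summary()` averages over the M(M−1)/2 unordered pairs, excluding
the self-distances that would bias the mean toward zero, and reports the
sample (n−1) standard deviation. At the set sizes this package targets
(hundreds of molecules, tens of thousands of pairs) the population/sample
distinction is far below reporting precision.

## Projections

Four methods, one contract: rows of the coordinate matrix align with the
input ids, and all quality statements are made about *pairwise distances*,
never raw coordinates, because every method's output is arbitrary up to
rotation, reflection and translation.

**PCooA** (classical MDS) double-centers the squared distance matrix,
B = −½ J D⁽²⁾ J, and eigen-decomposes. Because the convex-transformed
distances are non-Euclidean, negative eigenvalues are expected; they are
reported in full but excluded from coordinates (standard Gower treatment),
and the fraction of positive-eigenvalue variance represented is recorded.
Two numerical choices worth stating:

* *Sign convention.* Each eigenvector is flipped so its largest-magnitude
  entry is positive, making output identical across LAPACK builds.
* *Degenerate axes.* An eigenvalue that is zero within a relative tolerance
  of 10⁻⁹ (collinear configurations, duplicate points) yields a legitimate
  zero-width axis rather than an error; only a *genuinely negative*
  eigenvalue among the requested dimensions aborts, with the spectrum in
  the message. A strict "must be positive" rule would reject perfectly
  reasonable degenerate inputs like points on a line.

**Kruskal non-metric MDS** preserves only the rank order of distances. Each
iteration fits disparities by weighted isotonic regression (pool-adjacent
violators) of the configuration distances on the rank order of D, then
takes a Guttman-transform step, accepted only if stress-1 decreases, with
step halving otherwise — so the recorded stress trace is non-increasing by
construction. Tied input distances are pre-pooled into one block sharing a
single disparity (the "primary" tie treatment: deterministic, and the
classical choice). Stress is kept as a fraction in [0, 1]; the convergence
tolerance (default 10⁻³) is expressed on the percent scale, i.e. iteration
stops when an accepted step improves stress by less than 10⁻⁵ as a
fraction — matching the convention of the widely used reference
implementation so that configurations are comparable.

**Sammon mapping** minimizes the inverse-distance-weighted stress by the
classical diagonal pseudo-Newton update, scaled by `magic` (default 0.3,
the package's stated default; the step is guarded by halving on
non-descent, so `magic` trades speed for caution rather than correctness).
Because the loss divides by the original distances, zero off-diagonal
distances (duplicate molecules) are jittered to 10⁻⁹ with a warning — in
both iterative methods, and only there; PCooA handles duplicates natively.

**t-SNE** is implemented in-package (exact O(M²) version: per-point
precision calibrated by binary search to the target perplexity on squared
distances, symmetrized affinities, Student-t output kernel, gradient
descent with momentum 0.5→0.8, adaptive gains, early exaggeration ×12 for
250 iterations, learning rate 200). Defaults: perplexity 30 (requires
M ≥ 3·perplexity + 1), 1000 iterations, seed 1. Determinism given the seed
is part of the contract and is tested; different seeds legitimately give
different maps. For the few hundred molecules this package targets, the
exact gradient is fast enough that approximate (Barnes-Hut) schemes would
only add variance.

Both the initialization of KMDS and Sammon (the PCooA solution, unchanged)
and the `stress()` / `shepard()` diagnostics are shared across methods.
`stress()` is a pure evaluator of a given configuration against the
original distances — its "kruskal" flavour uses the configuration distances
directly (metric residual), which is what makes it useful as an
independent check; the optimizer's internal stress-1 uses disparities.
`shepard()` reports r² as the squared Pearson correlation between original
and projected pairwise distance vectors.

## Kernel density maps and the posterior

The two class maps use the 2D Gaussian product kernel with per-axis
Silverman bandwidths h = 1.06·min(σ̂, IQR/1.34)·M^(−1/5) (coordinate
units). Three decisions:

* *IQR reading.* The rule's R is taken as Q₃ − Q₁ by the standard
  linear-interpolation quartile convention. This matches the canonical
  normal-reference rule (and `stats::bw.nrd`, against which the
  implementation is tested); the halved alternative Q₃ − Q₂ would shrink
  every bandwidth by up to 2× and disagree with the heuristic's derivation.
* *Pooled bandwidths.* One pair (hx, hy) is computed from **all** training
  points and shared by both class maps. Unequal per-class bandwidths would
  make the likelihood ratio — hence the posterior — depend on which class
  happens to be smaller, an artifact rather than information.
* *Exact evaluation.* Densities are always the exact kernel sum; grids are
  evaluated exactly at their nodes and exist only for rendering. There is
  deliberately no interpolation path, so grid resolution can never change a
  classification (tested by comparing grid nodes against direct
  evaluation). A side effect worth noting for anyone comparing against
  grid-based KDE routines from other ecosystems: several popular 2D-KDE
  functions expect bandwidth arguments on a ×4 convention that they rescale
  internally; `psma` uses the Silverman value literally in the kernel, so
  absolute density heights can differ from such stacks by a fixed factor
  while the posterior — a ratio — is largely insensitive.

The posterior is the plain Bayes quotient p₊ = L₊π₊ / (L₊π₊ + L₋π₋) with
priors defaulting to training class frequencies (overridable). This is a
full 2D model: no independence of the two projected coordinates is
assumed, and the test suite contains a construction (class-dependently
correlated coordinates) on which the full-2D posterior and a
product-of-marginals posterior demonstrably disagree.

**Applicability domain.** Where the total mixture density falls below
10⁻¹² of its peak over the training support, both likelihoods are
numerically meaningless; such queries are flagged `in_domain = FALSE` and
fall back to the priors (their ROC score is the positive prior, so they
sort neutrally). The threshold is relative, not absolute, so rescaling the
coordinate units does not move the domain boundary.

## Out-of-sample embedding

The projection is approximated as a linear map D·T = C, solved as
T = D⁺·C with an SVD pseudo-inverse truncated at a relative singular-value
cutoff of 10⁻¹⁰. For full-rank D this is the literal inverse and training
points are reproduced exactly (asserted at 10⁻⁸ for all four methods);
for rank-deficient D (duplicate molecules) it is the least-norm solution
and the residual ‖DT − C‖∞ is recorded on the transform object. The same
T is used for every projection method, including t-SNE whose map is
genuinely non-linear — the linear T is then an approximation whose quality
decays with distance from the training support. This is a documented
limitation, not a bug: embedding quality far from the training set is
untested territory by construction.

## Evaluation

Splits are stratified by class by default. The package's reference world
has only dozens of positives; a plain 20% random split has a real chance
of leaving zero test positives, which makes AUC undefined, so
stratification is the default and plain random splitting remains available
for strict replication. ROC uses threshold sweeps over unique scores (ties
cross together) with trapezoidal integration, which is provably the
normalized Mann–Whitney pair-ranking statistic — the test suite asserts
exact equality against a brute-force pairwise oracle. MCC returns 0 on any
zero denominator factor (the field convention for degenerate tables).

# The synthetic world

`generate_clusters()` states the world the package is validated in:
cluster centroids at mutual distance `separation` (latent units), points
scattered with isotropic Gaussian noise `noise_sd`, positives in cluster 1,
an exact fraction `label_noise` of labels flipped, and latent Euclidean
distances mapped to similarities by the *algebraic inverse* of the convex
transform (after rescaling by the maximum pairwise distance ×(1 + 10⁻⁶) so
all similarities stay strictly positive — which keeps the fixtures legal
for the neglog/inverse transforms too). Running the forward transform on
the generated similarities reproduces the rescaled latent distances to
10⁻¹², so every pipeline stage can be checked against known ground truth.

Defaults are the reference recovery regime: 56 positives / 170 negatives
(the class shape of a real σ-receptor benchmark set), two clusters,
separation 10·noise_sd, no label noise. The named fixtures `tiny`
(20 molecules), `unbalanced` (the default shape) and `overlap`
(separation 2·noise_sd) cover speed, class-imbalance and hard-case
testing; all are labelled synthetic stand-ins for real similarity
matrices.

What a green test on this world does establish: the composed pipeline
recovers planted cluster structure through every projection method,
embeds held-out molecules correctly, and degrades to chance (AUC ≈ 0.5)
when the planted signal is removed. What it does not establish: behaviour
on real molecular similarity distributions, whose distance spectra are
narrower and heavily non-Euclidean, whose "clusters" are diffuse activity
regions rather than Gaussian blobs, and whose labels carry assay noise
with structure. The `overlap` fixture probes the direction of that gap
(depressed MCC at decent AUC) but does not close it.

# Known limitations

* PCooA on non-Euclidean distances is not an optimal 2D approximation;
  negative eigenvalues are discarded, not modelled.
* The linear embedding T is exact only on the training set; t-SNE
  embeddings in particular should be trusted only near training support.
* Bandwidths are global (no adaptive KDE) and Gaussian-only.
* The classifier is binary; multiclass surfaces and continuous-activity
  landscapes are out of scope.
* Real-data parity against published benchmark matrices requires those
  matrices, which do not ship with the package; the test suite therefore
  validates properties and parameter recovery, not literal reproduction of
  published tables.
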