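---
title: "Joint embedding of paired Hi-C matrices: model, parameters, and design"
author: "jointmds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint embedding of paired Hi-C matrices: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointmds)
```

## The problem

Hi-C measures pairwise contact frequencies between genomic bins. Under the
standard biophysical assumption that contact frequency decreases with mean
spatial distance, a single contact matrix determines (up to rigid motion and
reflection) an ensemble-average 3D structure, recoverable by multidimensional
scaling (MDS). Comparing *two* conditions — two cell types, two growth
conditions — asks a harder question: **which loci moved?** Embedding each
matrix separately and superposing the results is unstable, because MDS is
stochastic: two runs on the *same* matrix produce structures whose aligned
RMSD is far from zero, so per-locus differences between conditions are
contaminated by run-to-run noise.

`jointmds` instead embeds the two matrices *simultaneously*, with a penalty
that ties each locus's two positions together. The penalty strength (the
*similarity weight*) controls how much disagreement between the structures
the data must earn: differences that survive a substantial weight are
reproducible relocalizations rather than embedding noise.

## The model

Given two target-distance matrices $D_1, D_2$ over the same $N$ loci, the
fit minimizes the joint stress

$$\sigma(X_1, X_2) \;=\; \sum_{i<j}\big(d_{ij}(X_1)-\delta_{ij1}\big)^2
 + \sum_{i<j}\big(d_{ij}(X_2)-\delta_{ij2}\big)^2
 + \sum_i w_i\, d_i^2(X_1, X_2),$$

where $d_{ij}(X_c)$ is the embedded Euclidean distance, $\delta_{ijc}$ the
target, $w_i \ge 0$ the per-locus similarity weight (a single scalar in
practice), and $d_i(X_1,X_2)$ the distance between locus $i$'s two embedded
positions. Pairs with $\delta_{ijc}=0$ are treated as missing and excluded
from the fit term of that condition.

Minimization is by stress majorization (SMACOF). The MDS part of $\sigma$
is bounded above by a quadratic touching it at the current configuration
$Z$, whose minimizer is the Guttman transform $B(Z)Z/N$ with
$b_{ij} = -\delta_{ij}/d_{ij}(Z)$ for informative pairs, zero for missing
pairs or coincident points, and $b_{ii} = -\sum_{j\ne i} b_{ij}$. The
penalty term is already quadratic, so it needs no bound. Setting the
gradient of the combined surrogate to zero gives the update

$$X_1^{\text{new}} = (W+I)^{+}\big[\,W X_2 + B(X_1)X_1/N\,\big],$$

and symmetrically for $X_2$; with diagonal $W$ each row is simply the blend
$(w_i x_{2i} + g_i)/(w_i+1)$ of the similarity pull and the Guttman pull.
$w=0$ recovers plain SMACOF; $w \to \infty$ forces the structures to
coincide.

### Update order

Both structures are updated **simultaneously** from the previous
iteration's coordinates (a Jacobi block update), not sequentially. This has
two consequences we rely on. First, exchanging the two input matrices
exchanges the two output structures exactly, for any seed — the fit has no
hidden asymmetry. Second, descent is still guaranteed: the surrogate's
Hessian splits as blocks $(W+I)$ with coupling $-W$, and since
$(W+I)\pm W \succeq I$, simultaneous block minimization cannot increase the
surrogate, hence cannot increase the stress. The per-iteration stress trace
is stored on the fit object and asserted non-increasing in the test suite.

### Initialization, chirality, convergence

Each restart draws a single Gaussian configuration (scaled to the mean
target distance, column-centered) and starts *both* structures from it.
A shared start means the penalty never wastes iterations repairing an
arbitrary relative rotation between the two embeddings. The global
chirality of the pair is unidentifiable from distances — a mirrored
solution fits exactly as well — so no handedness is imposed; downstream
comparisons to external structures should test both chiralities.

Defaults: 4 restarts, at most 300 iterations each, stopping when the
relative stress decrease falls below $10^{-4}$ (common SMACOF practice) or
when stress reaches a numerical floor of $10^{-12} \times \sum \delta^2$
(without which a perfect fit would never trigger the relative test). The
restart with the lowest final stress wins; both structures are mean-centered
on output. All randomness flows from one integer seed.

### Missing pairs and the $1/N$ scaling

With complete distance matrices the $B(Z)Z/N$ update is an exact
majorization step and stress decrease is guaranteed. When pairs are
missing, $1/N$ is a conservative stand-in for the pseudo-inverse of the
weight Laplacian; in that regime stress increases of order $10^{-6}$
relative can occasionally appear late in a run. The preprocessing pipeline
makes this moot in practice: the distance-decay prior fills observed zeros,
so pipeline matrices are complete.

## Preprocessing

The pipeline runs in a fixed order:

1. **Locus intersection.** Loci with zero counts in *both* datasets are
   dropped from both; a locus informative in either dataset is kept in
   both. Intersecting first keeps later expected-contact estimates from
   being diluted by dead bins.
2. **Mean normalization.** Each matrix is divided by the mean of its
   nonzero entries, putting the two datasets on a common scale (required
   for the penalty and for rigid superposition to be meaningful).
3. **Distance-decay prior** (`k`, default 0.05): every within-span pair,
   including observed zeros, is shrunk toward the mean contact at its
   genomic separation, $c' = (1-k)\,c + k\,\bar c(s)$. This is deliberately
   mild — it preserves the matrix-wide mean exactly — but it regularizes
   sparse regions; without it embedded structures degenerate into tangles.
   Separations with no observed pairs contribute no prior. Normalizing
   before applying the prior makes `k` comparable across datasets; the
   order is fixed rather than configurable, so results are reproducible
   from the parameters alone.
4. **Distance conversion**: $\delta_{ij} = c_{ij}^{-1/4}$ by default, the
   inverse fourth-power law relating contacts to distances; the exponent is
   user-adjustable. Zero contacts become zero (missing) distances.

Hi-C bias correction (KR/ICE) is out of scope — inputs are assumed
normalized.

## Choosing the similarity weight

Reproducibility is measured as the mean pairwise Pearson correlation of
relocalization-magnitude profiles across repeated fits with different
seeds. `select_similarity_weight()` evaluates a candidate grid and picks
the smallest weight within 0.01 of the maximum observed reproducibility —
the start of the plateau, where extra weight no longer buys stability but
would start to flatten real differences. Weight zero is by definition
independent inference; at that point the two structures are inferred with
unrelated initializations and aligned afterwards with the Kabsch rotation,
so the zero point of the curve is the infer-then-align baseline. Typical
data plateau by weights of a few hundredths; the embedding error per
condition grows only marginally even at weight 0.5 because many structures
fit a noisy matrix near-equally well.

## Compartment analysis

Compartment scores are the loadings of the leading eigenvector of the
Pearson correlation matrix of the observed/expected contact matrix
(expected = separation-stratified mean, the same estimator as the prior),
scaled so the largest absolute score is 1. The eigenvector sign is
arbitrary; `orient_scores()` anchors the positive sign to whichever
compartment is more enriched for a user-supplied "active" mask (gene
density, an epigenomic annotation — we do not bundle any genome
segmentation). The PC1 variance fraction is reported as a diagnostic:
checkerboarded matrices concentrate variance in PC1, decay-only matrices
do not.

The 3D **compartment axis** of a structure is the direction best
predicting compartment scores from coordinates, fitted by linear
$\varepsilon$-insensitive support vector regression (cost 1,
$\varepsilon = 0$, no feature scaling; `e1071`). An ordinary-least-squares
variant (`method = "ols"`) exists for portability and agrees with the SVR
direction within a few degrees on well-behaved data. Since each structure
of a pair yields its own axis, the common axis is the normalized mean of
the two sign-aligned directions (fitting one regression on pooled
coordinates would be the alternative; averaging keeps the per-structure
fits inspectable, and the two directions agree to within a few degrees on
all our fixtures — a divergence beyond 60° triggers an instability
warning). The axis is completed to an orthonormal triad, per-locus
displacement fractions along each axis are divided by the axis length
(mean absolute centered projection, measured on the pooled coordinates of
both structures) to remove elongation bias, and a two-sided equal-variance
t test compares compartment-axis fractions against the pooled orthogonal
fractions. Zero-magnitude displacements are excluded (their fraction is
undefined).

## Relocalization peaks

Peaks in the magnitude profile are called by a continuous wavelet
transform: Ricker wavelets at widths 1–10 bins, ridge lines tracked from
the largest scale down (a maximum joins the nearest active ridge if within
width/4 bins; ridges may skip at most 2 scales). Ridges shorter than a
quarter of the width range, or with width-1 signal-to-noise below 1 (noise
= 10th percentile of absolute width-1 coefficients in a local window), are
discarded; ridges landing within 2 bins of a stronger one are merged. A
peak's position is its ridge's index at the smallest width; the largest
width on the ridge is recorded as its width class. A constant profile has
no peaks by definition and short-circuits the transform. Peaks whose locus
shows an absolute compartment-score difference of 0.2 or more are filtered
out (strict inequality below threshold retains), separating within-
compartment relocalization from compartment switching; the remainder is
partitioned into intra-A, intra-B, and discordant sets.

## Synthetic fixtures: what they emulate, and what they do not

All validation runs on generated data with planted ground truth:

* `make_reloc_pair` — a helix of 50 loci, contacts $c = d^{-4}$ with
  log-normal noise (SD 0.1), one locus displaced by 2 units (twice the
  helix radius) in condition B. Tests that a single relocated locus tops
  the relocalization profile.
* `make_boundary_pair` — 200 bins, two interaction domains over a
  $1/(1+s)$ decay baseline (expected short-range count 100, Poisson
  noise), within-domain enrichment 3, boundary at bin 100 vs bin 105: a
  shift of 2.5% of the span, the same order as a 1 Mb boundary shift on a
  ~48 Mb chromosome. Tests that the joint mode localizes the differential
  boundary while the infer-then-align baseline does not.
* `make_compartment_pair` — 100 bins in alternating A/B blocks of 10,
  same-compartment enrichment 2, cross-compartment depletion 1/2,
  log-normal noise (SD 0.2); condition B flips loci 41–50. Tests that
  relocalization concentrates along the compartment axis exactly when a
  flip is planted, and not on replicate (no-flip) pairs.

These block models reproduce the *logic* of the corresponding experiments
at matrix level. They do not emulate read-level artifacts (restriction
fragments, mappability, ligation noise), unbalanced coverage between
conditions, translocations, or interchromosomal contacts — passing tests
say the algorithm recovers planted signals under idealized noise, not that
any particular biological dataset will behave as cleanly.

## Problem sizes and runtimes

The test suite and the acceptance script run fixtures of 10–200 loci, 1–4
restarts, and 5–20 replicate seeds per claim — sizes chosen so the whole
validation executes in minutes on one core while keeping every planted
effect comfortably above its detection threshold. Chromosome-scale
matrices (thousands of bins at 100 kb–10 kb) are within reach of the same
code path since every iteration is $O(N^2)$ dense linear algebra, but no
partitioned/hierarchical approximation is provided.

## Known limitations

* Global chirality of the structure pair is unidentifiable; only
  *relative* geometry is meaningful.
* Reported relocalization is in embedding units, comparable between the
  two conditions of one fit but not across fits without care (mean
  normalization fixes the scale only up to the data's own dispersion).
* The equal-variance t test in the axis decomposition treats loci as
  independent; neighboring bins are correlated, so its p-value is a
  ranking diagnostic rather than a calibrated genome-wide error rate.
* Only intrachromosomal matrices are handled; `.hic`/`.cool` binary
  readers are an extension point, not implemented.
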