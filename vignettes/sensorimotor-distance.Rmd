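---
title: "Sensorimotor distance: model, measures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensorimotor distance: model, measures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smdistance)
```

## The model

Grounded accounts of semantic memory hold that a concept's representation
partially replays the perception and action experience associated with it.
Sensorimotor strength norms operationalise this: for each concept, raters
judge on a 0–5 scale how strongly the concept is experienced through each
of six perceptual modalities (auditory, gustatory, haptic, interoceptive,
olfactory, visual) and five action effectors (foot/leg, hand/arm, head,
mouth/throat, torso). Each concept is then a point in an 11-dimensional
space of mean ratings, and dissimilarity between two concepts is a distance
between their vectors:

$$ d_{\cos}(u, v) \;=\; 1 - \frac{u \cdot v}{\lVert u\rVert\,\lVert v\rVert}. $$

Cosine distance is the principal measure: for non-negative ratings it lies
in $[0, 1]$, is invariant to the overall intensity of a profile (only the
*mix* of modalities matters), and in validation work it models human
similarity judgements at least as well as the alternatives. Four
alternatives are provided for sensitivity analyses:

* **correlation** — $1 - r(u, v)$, Pearson correlation across the 11
  dimensions of the pair;
* **euclidean** — $\lVert u - v \rVert_2$;
* **minkowski3** — $(\sum_i |u_i - v_i|^3)^{1/3}$;
* **mahalanobis** — $\sqrt{(u-v)^\top \Sigma^{+} (u-v)}$, which whitens
  the dimensions' intercorrelational structure (things that can be touched
  can usually be seen) using the covariance $\Sigma$ of the rating
  dimensions across concepts.

Two choices in the Mahalanobis branch are deliberate. The covariance is
estimated **once from the whole loaded table** (unbiased $n-1$
denominator), not per pair, because the measure is meant to impose a single
global geometry on the space. Its inverse is the **Moore–Penrose
pseudo-inverse** (`MASS::ginv`): identical to the plain inverse when the
covariance is well conditioned, and still defined when a dimension is
nearly linearly dependent on the others.

Degenerate inputs are errors, not sentinels: an all-zero vector has no
direction, so cosine distance raises a classed error rather than silently
returning a default that would contaminate extreme-pair scans; likewise a
constant vector under the correlation metric. Distances are computed in
double precision on the raw mean ratings — no z-scoring or other
standardisation is applied before cosine, since the measure is defined on
the rating scale itself.

## Words and keys

Norms distribute words in upper case, benchmarks in lower case, and the
analyses require joining across both, so all lookups go through one
normalisation: case-folding, trimming, and collapsing internal whitespace
runs ("soap opera" stays a single two-word item; there is no tokenisation).
Duplicate keys in a norms file are a hard error rather than last-wins,
because a silent overwrite would corrupt every downstream pair statistic.

## Scanning 788 million pairs

The published vocabulary of 39,707 concepts yields
$\binom{39707}{2} = 788{,}303{,}071$ unordered pairs — far too many to
materialise. `summarize_distances()` therefore streams the pair space in
blocks of `chunk_size` rows: rows are pre-transformed once per metric (unit
vectors for cosine/correlation, whitened coordinates for Mahalanobis), so
each block reduces to one dense cross-product. Accumulators are
per-block sums combined with Kahan compensation (788 million additions in
double precision need stable summation); the extreme-pair lists are bounded
top-$k$ merges ($k = 100$ by default, comfortably covering any published
extreme pairs); and the result is provably independent of `chunk_size`
(tested for chunk sizes 1, 7, 64 and $n$). The reported SD uses the
population ($/N$) convention, so a single-pair table reports an SD of 0.

Histograms use fixed bins decided **before** the scan, so one pass
suffices and counts always sum to the pair count: width .01 on $[0,1]$ for
cosine, and 100 equal bins from 0 to an a-priori upper bound implied by
the 0–5 rating scale for the others (2 for correlation; $\sqrt{11 \cdot
5^2}$ for Euclidean; $(11 \cdot 5^3)^{1/3}$ for Minkowski-3; and
$\sqrt{\lambda_{\max}(\Sigma^{+}) \cdot 11 \cdot 5^2}$ for Mahalanobis).
Binning to the observed maximum would have required a second pass; the
fixed bound keeps the scan single-pass at the cost of some empty upper
bins.

Ties are broken lexicographically on the normalised keys everywhere
(extreme pairs, neighbour ranks): published analyses report single extreme
pairs without a tie rule, and determinism is required for testing.

Nearest-neighbour search is an exact scan — at $n \approx 40\,000$ a full
pass is cheap, so no approximate indexing is used or needed.

## 2-D layouts

`sammon_layout()` minimises the Sammon stress

$$ E \;=\; \frac{1}{\sum_{i<j} d^*_{ij}} \sum_{i<j}
   \frac{(d^*_{ij} - d_{ij})^2}{d^*_{ij}}, $$

with $d^*$ the input sensorimotor distances and $d$ the layout Euclidean
distances. The literature this package serves sometimes labels the Sammon
technique "nonmetric MDS", but Sammon's mapping is a metric method with a
fully specified stress function — which is exactly why we implement this
stress rather than one of the many genuinely nonmetric variants; published
layout figures are consequently reproducible at the level of cluster
structure, not exact coordinates.

Numerical choices: the initial configuration is classical scaling
(eigendecomposition of the doubly centred squared-distance matrix) when it
yields two usable axes, else a seeded random configuration; descent is
plain gradient descent with a backtracking line search, so a step is only
accepted when it lowers the stress and the stress trace is non-increasing
by construction; iteration stops after `max_iter` (default 500) accepted
steps or when the relative improvement drops below `tol` (default 1e-9);
exact-zero input distances (duplicate profiles) are perturbed to 1e-9 to
keep the stress defined. Identical inputs and seed give bit-identical
layouts. The coordinates CSV plus its JSON sidecar (stress, seed,
iterations) is the canonical output; plotting is left to the user.

## Benchmark evaluation

Validation joins the norms to word-pair benchmarks with human similarity
scores (SimLex-999, WordSim-353, MEN dialects are supported, plus a generic
`word1,word2,score` layout). Coverage is reported rather than silently
filtered: pairs with either word missing from the norms are flagged, not
dropped, and each statistic is computed listwise on the rows jointly
covered by exactly the variables it uses.

The original validation analyses used Bayesian correlations and
hierarchical Bayesian regressions. This package deliberately reports the
**frequentist point estimates** of the same quantities — Pearson $r$, OLS
$R^2$, and the incremental $\Delta R^2$ when sensorimotor distance enters
at step 2 above an alternative predictor — because the point estimates are
the reproducible, toolbox-independent surface (under the uniform prior
used for the published correlations, the posterior point estimate
coincides with Pearson $r$). Bayes factors and credible intervals are out
of scope. Since the step-2 model nests the step-1 model on identical rows,
$\Delta R^2 \ge 0$ always; an exact duplicate of the distance column at
step 1 is the well-defined "no unique variance" case ($\Delta R^2 = 0$),
while any *other* perfectly collinear predictor pair is rejected as
degenerate.

Best-subset search enumerates all $2^p - 1$ non-empty predictor subsets
(capped at $p \le 12$) on the rows jointly covered by all candidates, and
ranks them by a Schwarz (BIC-type) criterion,
$n \log(\mathrm{RSS}/n) + (k+2)\log n$. The RSS is floored at
$10^{-12} \cdot \mathrm{TSS}$ so that a saturated fit ($R^2 = 1$) does not
produce an unbounded criterion; among equally perfect subsets the
parameter penalty then prefers the smaller one, and remaining ties break
toward fewer predictors, then lexicographically.

The abstract/concrete analysis splits pairs by a concreteness map on a
1–5 scale at the midpoint: a word rated strictly below 3 is abstract, at
or above 3 concrete (so exactly 3.0 is concrete); pairs with a missing
rating go to an `unsplit` bucket rather than silently vanishing.

## What the synthetic generator does and does not emulate

`generate_norms_fixture()` draws latent vectors from a multivariate normal
with a block covariance template — 0.5 within the six perceptual
dimensions, 0.4 within the five effector dimensions, 0.2 across blocks,
unit diagonal — centred at 2.5 (the scale midpoint) with unit latent SD,
then clips into $[0, 5]$. This was chosen once as the simplest mechanism
producing realistic inter-dimension correlation structure; the clipping
affects roughly 1% of values per tail and slightly shrinks variances,
which is acceptable for testing. It does **not** attempt to match the
published norms' marginal distributions, their dominant-modality
structure, or their word-frequency composition — so passing tests
demonstrate the correctness of the machinery (metrics, streaming scan,
ranking, regression), not the empirical values of the published pair
space: the synthetic mean cosine distance (~0.10) is smaller than the
published table's (~0.195), as expected for a homogeneous Gaussian cloud.

`generate_benchmark_fixture()` samples unordered pairs without replacement
and sets each human score to a monotone function (identity by default) of
cosine *similarity* plus Gaussian noise, recording the generative
parameters. This gives three exact recovery targets: $r = -1$ against
cosine distance in the noiseless limit, the closed-form attenuation
$|r_{\mathrm{obs}}| = \sigma_s / \sqrt{\sigma_s^2 + \sigma_\varepsilon^2}$
across a noise grid, and $|r| \to 0$ under overwhelming noise.

## Problem sizes and tolerances

The default test and verification runs use 100–300-word synthetic tables
(5,000–45,000 pairs) for oracle comparisons, 2,000-pair benchmarks for the
attenuation grid, and a 1,000-word table (499,500 pairs) for the
whole-pipeline summary in `scripts/acceptance.R` — sizes at which the
brute-force double-loop oracles stay exact and the full suite runs in a
few minutes. Streaming agreement with the oracle is asserted to 1e-10;
Sammon recovery of exactly embeddable configurations to 1e-3 on the
distance matrix. The full 39,707-word scan is supported by the same code
path (a ~40k-row synthetic table streams in well under an hour on one
core) but the published distributional values can only be reproduced with
the published norms file itself, which the package does not redistribute.

## Known limitations

* Only the 11 mean ratings feed the distance; ancillary norms variables
  (dominant modality, exclusivity, ...) are ignored by design.
* The Mahalanobis covariance is assumed estimable from the loaded table as
  a whole; no per-subset geometry is offered.
* The correlation metric treats the 11 dimensions as an unordered sample
  of paired observations — its usual caveat, inherited here.
* Best-subset ranking uses a BIC-type criterion as a deterministic proxy
  for posterior model comparison; it will not always agree with
  Bayes-factor rankings near ties.
* MEN-style forced-choice scores are consumed as published single scores;
  the conversion from choices to scores is upstream of this package.
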