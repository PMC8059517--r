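---
title: "Methods: decomposed beta-diversity in three dimensions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decomposed beta-diversity in three dimensions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elevbeta)
```

## The model

All of the package's dissimilarities are built from one algebra. For an
unordered pair of assemblages with matching components $a$ (shared), $b$,
$c$ (unique to either side):

$$\beta_{sor} = \frac{b+c}{2a+b+c}, \qquad
  \beta_{sim} = \frac{\min(b,c)}{a+\min(b,c)}, \qquad
  \beta_{sne} = \beta_{sor} - \beta_{sim}.$$

$\beta_{sim}$ (Simpson dissimilarity) captures replacement and is blind to
richness differences; $\beta_{sne}$ captures the extra dissimilarity caused
by one assemblage being a subset of the other; the two add exactly to the
total. The package computes $\beta_{sne}$ *as the difference*, so
additivity holds to machine precision by construction, and the components
$a,b,c$ stay on their natural scale (integers, branch lengths, areas) with
division happening once per index.

The three dimensions differ only in what $a,b,c$ measure:

* **Taxonomic** — species counts from the presence/absence matrix.
* **Phylogenetic** — branch lengths on the tree pruned to the regional pool
  (the union of species over all sites). Each branch is classified by
  whether at least one descendant tip occurs in each community; $a$ is the
  summed length of branches on both communities' root-to-tip paths, $b$ and
  $c$ the lengths exclusive to each. The root stem, if present in the file,
  carries no information about any pair and is dropped. On a star tree with
  unit branches this reduces exactly to the taxonomic case, which the test
  suite exploits as an oracle.
* **Functional** — areas in a two-dimensional trait space. Each trait is
  natural-log transformed (size measurements are ratio-scale and
  right-skewed) and z-scored, making the PCA correlation-based; species
  coordinates are the first two component scores. A community is the convex
  hull of its species' points; $a$ is the intersection area of the two
  hulls (Sutherland–Hodgman clipping of convex polygons, shoelace area),
  $b$ and $c$ the areas unique to each hull.

### Assumptions

* Incidence data: presence/absence only; detection is taken at face value.
* The phylogeny is rooted, fully lengthed, and covers every species present
  (unmatched species are a hard error unless pruning is explicitly
  requested — the pruned list is logged, never silent).
* The 2-D trait space is an adequate summary; the generator's shared
  size-factor traits give first-two-axes variance fractions in the
  90–100% range, comparable to real morphometric tables.
* Pairwise regressions treat pairs as independent, which they are not; see
  Limitations.

## Standardized effect sizes

`ses_beta()` compares each observed index with its distribution over
`n_rand` randomizations: $SES = (obs - \bar{x}_{null})/s_{null}$. Scheme
defaults are chosen per dimension and always recorded in the output rather
than presented as the only correct choice:

* taxonomic: `fixed_fixed_swap` — sequential 2×2 checkerboard swaps
  preserving both site richness and species occupancy (the conservative
  community null), with 10 000 burn-in swaps and 1 000 swaps between
  retained matrices;
* phylogenetic and functional: `label_shuffle` — the matrix is untouched
  and only the tip-label/coordinate assignment is permuted, isolating
  tree or trait structure from occupancy structure.

Both margins are asserted after every swap draw. Randomization happens in a
canonical (sorted) site/species order and is mapped back, so the same seed
gives a bitwise-identical SES table no matter how the input rows and
columns are ordered. Pairs whose null sd is zero keep `SES = NA` and are
flagged; a null that is constant for *every* pair raises a diagnostic
error. Calibration is a tested property: when the data are themselves drawn
from the richness-preserving null, SES over 100 replicates at
`n_rand = 999` has mean within ±0.15 and an $|SES|>1.96$ rate between 2%
and 9%.

## Blomberg's K

With trait vector $x$, phylogenetic covariance $V$ and phylogenetic mean
$\hat a = (\mathbf{1}'V^{-1}x)/(\mathbf{1}'V^{-1}\mathbf{1})$:

$$K = \frac{MSE_0/MSE}{E[MSE_0/MSE]}, \quad
  E\!\left[\frac{MSE_0}{MSE}\right]
  = \frac{\operatorname{tr}(V) - n/(\mathbf{1}'V^{-1}\mathbf{1})}{n-1}.$$

On a star tree $V \propto I$ forces $K = 1$ for any trait — the suite
checks this closed form to 1e-12 — and Brownian traits on 100-tip Yule
trees average $K \approx 1$. The permutation p-value uses
$(1+\text{hits})/(1+n_{perm})$ so it is never exactly zero; a singular $V$
(zero-length cherries) is reported with a remediation hint rather than
silently regularized.

## Comparative statistics

* **Wilcoxon rank-sum, reported as z.** Average ranks for ties,
  tie-corrected variance, *no continuity correction*, two-sided normal p.
  The field convention reports $|z|$; the sign (first sample higher /
  lower) is kept alongside. An exact-enumeration p over all
  $\binom{n_1+n_2}{n_1}$ assignments is available as a cross-check for
  pooled $n \le 16$. The normal approximation and the exact p can disagree
  by far more than a naive reader might expect at small $n$ (worst-case
  gaps of 0.07–0.24 for pooled $n \le 12$ over the full support); the
  package therefore treats the exact mode as the reference for tiny
  samples.
* **Distance decay.** OLS of an index on pairwise absolute elevation
  difference (metres); slope $S$ has units dissimilarity · m⁻¹. Fits with
  slope p above `alpha` are excluded from cross-group rankings and listed
  separately; exact slope ties share a rank in stable input order.
* **Forward AIC.** $AIC = n\ln(RSS/n) + 2k$ with $k$ counting intercept and
  slopes; greedy forward additions, stopping at the first non-improvement,
  ties broken by input column order, trajectory strictly decreasing by
  construction. Candidate predictors are pairwise absolute differences of
  the site-level variables (AMT, AP, AMH, NPP, PET); perfectly collinear
  candidates are dropped up front with a warning. A note on the stopping
  rule: with the 2-unit penalty, each pure-noise candidate is selected with
  probability ≈ 0.16, so "intercept-only on noise" is the *majority*
  outcome only for small candidate sets (the property test uses two
  candidates); with five noise candidates at least one is selected more
  often than not. This is a property of forward-AIC itself, worth knowing
  before reading selected models causally.
* **Climate interpolation.** Per site, linear interpolation of each
  variable between the two stations nearest in elevation; sites outside
  their span are extrapolated and flagged; two nearest stations at the same
  elevation are an error rather than a 0/0.

## The synthetic gradient

`simulate_metacommunity()` is the package's stand-in for field data and the
source of every end-to-end expectation. Sites are equally spaced over the
configured span (default 17 sites, 2000–4500 m — a ~2500 m transect with
the richest preset's site count; presets mirror designs of 17, 9 and 11
sites with 116, 14 and 18 species and 6, 5, 2 traits). Species have
contiguous elevational ranges in one of three geometries:

* **turnover** — equal breadths (default 600 m), midpoints staggered across
  the gradient: any pair of sites farther apart than the breadth shares no
  species, forcing $\beta_{sim}=1,\ \beta_{sne}=0$ there. These guarantees
  are checked exactly on every generated dataset, not sampled.
* **nested** — every range starts at the gradient base; a species is
  present wherever elevation ≤ its upper limit, so each higher site is a
  strict subset and $\beta_{sim}=0$ on all pairs.
* **mixed** — uniform midpoints, breadths drawn U(400, 1500) m; no closed
  form, flagged as such by `expected_behaviour()`.

The phylogeny is pure-birth; traits are Brownian with a shared size factor
(loading 0.9) plus trait-specific deviations (0.35), exponentiated around
taxon-typical baselines so they are positive and log-normal. The coupling
κ blends a Brownian position trait with independent noise and maps it
*linearly* onto the gradient, so at κ = 1 the range midpoint inherits the
Brownian trait's K exactly (mean K within [0.8, 1.2] over replicates) and
at κ = 0 the signal collapses. Environment: AMT falls at 5.5 °C km⁻¹ from
12 °C at the base; AP, AMH and PET decline monotonically; NPP is
hump-shaped at mid-elevation (to exercise non-monotone predictor
selection); all with seeded Gaussian noise scaled by `env_noise_sd`.

What the generator does *not* emulate: detection error, abundance
structure, dispersal dynamics, range fragmentation, and spatial
autocorrelation beyond the shared gradient. Passing tests therefore
demonstrate algorithmic correctness and calibration under known geometry —
not that any field system behaves this way.

## Numerical choices

* Additivity is exact by construction; the suite still asserts
  $|\beta_{sor}-\beta_{sim}-\beta_{sne}| < 10^{-12}$ everywhere.
* Hull components: $b$ and $c$ are clamped to 0 when within $10^{-9}$
  below it (floating-point seepage from clipping); the intersection is
  clamped at $\min(V_1,V_2)$. Collinear (zero-area) hulls are *excluded,
  not jittered* — jitter would silently change results. The half-plane
  test uses an $10^{-12}$ tolerance on the cross product.
* Communities below 3 species never enter the functional dimension
  (a planar hull needs $d+1$ points); the exclusion reason is recorded
  per pair.
* Pairs with one empty assemblage are excluded by default
  ($\beta_{sim}$ is 0/0 there); the `as_one` policy instead records total
  dissimilarity 1 with undefined components, for analyses that want the
  empty-site pairs retained.
* Axis signs in the trait PCA are fixed (largest-magnitude loading
  positive) so scores are reproducible across BLAS implementations.
* All seeds are mandatory where randomness exists; derived sub-seeds stay
  below $2^{31}$.

## Open design points, resolved

* *Tree distributions*: analyses over a sample of trees average the
  per-tree indices (`multi_tree_summary()`, with across-tree sd columns)
  rather than using a consensus tree; a single tree is the degenerate case.
* *Cross-dimension comparisons*: because the functional dimension only
  exists for ≥3-species communities, comparisons between dimensions default
  to the pairs computable in *both* dimensions, applied to both sides; the
  full-subset-per-dimension variant is a flag.
* *Trait-space scope*: the PCA is computed on the full trait table supplied
  for a group, not re-fit per community subset, so coordinates are
  comparable across all pairs of that group.
* *Predictor form*: environmental predictors enter as pairwise absolute
  differences of site values.

## Problem sizes

The shipped test suite runs its oracles at: exhaustive 6-species worlds
(4096 ordered pairs) for the decomposition; 200 random community pairs on a
20-tip star tree; 50 random convex polygon pairs against a $10^5$-point
Monte-Carlo estimate (within 3 standard errors, with an add-one-adjusted
se so sliver intersections cannot produce a degenerate zero bound); 100
null-calibration replicates at `n_rand = 999` on 8×20 matrices; 200
Brownian replicates on 100-tip trees for K; and 100 seeded runs per range
geometry for the headline turnover/nestedness contrast.

## Limitations

* Pairwise-only: no multiple-site Sørensen family, no abundance-based
  (Bray–Curtis) decomposition.
* Functional beta is strictly 2-D; higher-dimensional hull volumes and
  kernel hypervolumes are out of scope, as are abundance-weighted variants.
* OLS on pairwise distances ignores the non-independence of pairs sharing
  a site; p-values for decay slopes are therefore optimistic. A
  Mantel-style permutation would be the defensible alternative where this
  matters.
* No multiple-testing correction is applied across the many comparisons a
  full pipeline run produces; the output tables are the place to apply one.
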