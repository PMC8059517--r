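# elevbeta

Comparative decomposition of beta-diversity along elevational gradients, in
three dimensions at once: taxonomic, phylogenetic and functional.

## The problem

How community composition changes between sites ("beta-diversity") can come
from two very different processes: **turnover** — species at one site being
*replaced* by others at the next — and **nestedness** — the poorer site
simply holding an ordered subset of the richer one. Along mountain slopes
the balance between the two, and whether it looks the same when species are
weighted by their evolutionary history or their functional traits, is the
central question this package serves. It is aimed at community ecologists
working with site-by-species presence/absence matrices collected along a
gradient, plus (optionally) a phylogeny and a table of morphological
measurements.

## The statistics

For an unordered pair of assemblages, with matching components *a* (shared),
*b* and *c* (unique to each side), the package computes the pairwise
Sørensen dissimilarity and its additive partition:

- total: β_sor = (b + c) / (2a + b + c)
- turnover (Simpson dissimilarity): β_sim = min(b, c) / (a + min(b, c))
- nestedness-resultant: β_sne = β_sor − β_sim

The same three formulas are applied in three dimensions, changing only what
*a*, *b*, *c* measure:

| dimension | a, b, c are ... |
|---|---|
| taxonomic | species counts |
| phylogenetic (PhyloSor family) | shared/unique branch lengths on the pooled tree |
| functional (convex-hull) | intersection/unique hull areas in a 2-D PCA trait space |

Around the core sit: null-model **standardized effect sizes**
(SES = (obs − null mean)/null sd; schemes: fixed-fixed checkerboard swap,
richness-preserving draw, label shuffle), **Blomberg's K** phylogenetic
signal, two-sided **Wilcoxon rank-sum** comparisons (components within a
dimension, components across dimensions), **distance-decay regressions** of
dissimilarity on elevational distance with cross-group slope ranking,
forward-**AIC** selection of environmental-distance predictors, and
station-based climate interpolation. A seeded **synthetic-gradient
generator** produces metacommunities whose range geometry *forces* pure
turnover or pure nestedness, which is how the whole stack is validated.

## Worked example

```r
library(elevbeta)

# a 9-site, 14-species gradient with staggered (turnover-dominated) ranges
ds <- simulate_metacommunity(
  preset_config("like_rodents", seed = 42, mode = "turnover"))

bt <- beta_matrix_taxonomic(ds$community)
bt
#> pairwise_beta (taxonomic): 36 pairs, 0 excluded
#>   site_i site_j a b c beta_sim beta_sne beta_sor excluded reason
#> 1 site01 site02 1 1 2   0.5000      0.1   0.6000    FALSE
#> 2 site01 site03 0 2 3   1.0000      0.0   1.0000    FALSE
#> 3 site02 site03 2 1 1   0.3333      0.0   0.3333    FALSE
#> ...

# is turnover really the larger component here?
wilcoxon_z(bt$beta_sim, bt$beta_sne)
#> Wilcoxon rank-sum: |z| = 7.900, p = 2.78e-15 (n1 = 36, n2 = 36, tie-corrected)

# does dissimilarity grow with elevational distance, and how fast?
distance_decay(bt, ds$sites, "beta_sor")
#> distance decay of beta_sor: S = 2.103e-04 per m, p = 9.315e-05, r2 = 0.366 (36 pairs)

# standardized against the fixed-fixed swap null
ses_beta(ds$community, "taxonomic", n_rand = 199, seed = 1)
#> ses_table (taxonomic, scheme fixed_fixed_swap, 199 randomizations): 108 rows
#>   site_i site_j index observed null_mean null_sd     ses ...
#> 1 site01 site02   sim   0.5000    0.8668  0.2433 -1.5077
#> 3 site02 site03   sim   0.3333    0.8794  0.1803 -3.0281
#> ...
```

Reading the output: pair `site01`–`site03` shares no species (`a = 0`), so
its dissimilarity is pure turnover (β_sim = 1, β_sne = 0) — the staggered
geometry guarantees this for every pair further apart than the range
breadth. The Wilcoxon z confirms β_sim dominates β_sne across pairs; the
decay slope S ≈ 2.1 × 10⁻⁴ per metre says two sites 1000 m apart differ by
an extra ~0.21 in total dissimilarity; and negative SES values mark pairs
*less* dissimilar than the swap null expects (an environmental-filtering
signature).

`run_pipeline()` chains all of the above (three dimensions, SES,
three-level comparisons, slope rankings, AIC selection) for several species
groups at once and writes tidy CSVs, a data dictionary, a summary and a
seeded manifest.

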