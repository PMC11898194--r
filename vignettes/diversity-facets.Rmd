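---
title: "Multi-facet diversity analysis on gridded landscapes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-facet diversity analysis on gridded landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divfacets)
```

## The analysis

`divfacets` implements a complete macroecological workflow for asking how
taxonomic, functional and phylogenetic diversity of species assemblages are
distributed over a landscape and what environmental factors drive them. The
motivating setting is a montane biodiversity hotspot in which expert-drawn
range maps, a species trait table and a dated phylogeny are overlaid on a
regular grid of square cells:

1. **Community assembly.** Each species' range polygon is intersected with
   the grid; a cell is occupied when the intersection has positive area.
   Occurrences are then refined by the species' elevation limits and
   tolerated habitat types (extent-of-occurrence maps overestimate true
   occupancy), and species with incomplete trait data are dropped so the
   same retained pool underlies all three facets.
2. **Diversity facets.** Per cell: species richness (column sums of the
   presence matrix); functional richness (FRic), the convex-hull volume of
   the assemblage in standardized trait space; and Faith's phylogenetic
   diversity (PD), the branch-length sum of the minimal root-inclusive
   subtree spanning the assemblage.
3. **Richness control.** FRic and PD increase mechanically with richness,
   so both are standardized against Curveball null communities that
   preserve every species' occupancy and every cell's richness:
   `SES = (obs − mean_null) / sd_null`. Cells with `SES > 1.96` are
   overdispersed, `SES < −1.96` underdispersed.
4. **Inference.** Per-cell predictors (current climate, Last Glacial
   Maximum anomalies averaged over three GCMs, land-use proportions,
   topographic heterogeneity) are screened for collinearity
   (pairwise `|r| < 0.7`, then VIF `< 5`), z-scored, and related to each
   facet by generalized least squares with an exponential spatial
   correlation structure on cell centroids. Spatial correlations between
   facets use Dutilleul's modified t-test; differences among mountain
   regions use Kruskal–Wallis and Dunn tests with a compact-letter display.

Because real range maps, climate rasters and trait databases cannot ship
with a package, a seeded synthetic-landscape generator supplies a complete
study system with the statistical structure the analysis assumes. All
stages run end-to-end on synthetic data and every algorithmic component is
tested against independent oracles.

## The synthetic study system

`landscape_config()` fixes the study conditions; `synthesize_study()` is a
pure function of it. The default system is a 20 × 20 grid of 5 × 5 km
cells (400 cells) and a 600-species pool:

* **Surfaces.** Every environmental surface is seeded white noise smoothed
  by an isotropic Gaussian kernel (scale `autocorr_length_cells = 3`
  cells) and rescaled to a variable-appropriate range (elevation
  500–4500 m, MAT −2–18 °C, AP 400–1600 mm). A kernel-smoothed field is
  cheaper than a Gaussian-process draw and gives the one property the
  analysis needs: tunable spatial autocorrelation. Temperature is
  three-quarters elevational lapse and one-quarter mesoclimatic noise, as
  in real mountain systems; this matters because elevation itself is not a
  predictor, and without the lapse coupling the elevation signal that
  range refinement imprints on richness would be an unexplainable smooth
  residual. Land-use fields vary at half the climate correlation length;
  each class proportion is a capped logistic transform of its own latent
  field (forest ≤ 0.55, cropland ≤ 0.35, urban green space ≤ 0.10), so
  proportions are mutually independent and sum to less than 1.
* **Habitat.** Three elevation bands (terciles) — lowland, montane,
  alpine — which deliberately confounds habitat with elevation.
* **Ranges.** Axis-aligned rectangles, 5–18% of the extent per side.
  Centres are sampled with density
  `exp(g · east) · plogis((b_f z_forest + b_c z_cropland + b_T z_MAT)/1.5)`:
  an explicit east–west gradient (`g = 0.5`) times a bounded suitability
  link. The bounded link is a deliberate choice: with an unbounded
  exponential, a single best cell absorbs a large share of all range
  centres, producing assemblages of hundreds of species in one cell and
  none nearby — a pathology, not a gradient. Defaults inject a positive
  forest effect (+1.5), a negative cropland effect (−1.75) and a weak
  positive temperature effect (+0.3) on the placement log-density; the
  spatial regression recovers the two land-use signs with about 90–95%
  power at 400 cells, measured over 30 seeds. Elevation limits are the
  5th–95th percentile of elevation under the rectangle; tolerated habitats
  are the codes covering ≥ 15% of its cells (always including the mode).
* **Traits.** Nine mammal traits from a multivariate log-normal with
  realistic scales; the designated pairs hindfoot/tail length and body
  length/body mass get log-scale correlation `trait_corr = 0.5`. A
  fraction `missing_trait_frac = 0.2` of species receives one missing
  value — matching the roughly one-fifth exclusion rate typical of mammal
  trait compilations — to exercise the completeness filter.
* **Phylogeny.** A Yule (pure-birth) tree conditioned on the species
  count, tips `sp0001…`.
* **Predictors.** The eight-variable set the screen should retain (MAT,
  AP, two LGM anomalies, three land-use proportions, elevation SD) plus a
  deliberately collinear `elev_range` column (r ≈ 1 with elevation SD)
  that the pairwise stage must remove — mirroring how topographic
  heterogeneity candidates are near-duplicates in practice.
* **Seeds.** One root seed; every component derives a fixed-offset child
  seed, so changing one component's draw count never perturbs another.

What the generator does **not** emulate: irregular range shapes, spatial
trait structure (trait values are independent of geography), phylogenetic
trait signal, observation error, and real covariance between climate and
land use. Passing tests therefore demonstrate algorithmic correctness and
statistical calibration under a known, well-behaved data-generating
process — not robustness to every pathology of real atlas data.

## Numerical and statistical choices

**Convex hulls.** FRic needs exact hull volumes in up to nine dimensions;
the package implements an incremental (beneath-beyond) hull with
simplicial facets in compiled code. Facet hyperplanes come from Gaussian
elimination with partial pivoting; points within `1e-9 · scale` of a facet
are treated as coplanar and absorbed; affinely degenerate point sets
return volume 0 with a `degenerate` flag rather than an error, because
null-model assemblages can be degenerate after reduction and downstream
code needs a value. Volumes agree with an independent qhull implementation
to well below 1% on random point sets.

**Trait space.** Body mass and the three length traits are log10
transformed (mammal size traits are log-normal), every trait is z-scored
across the *retained pool* (not per cell, so cells are comparable), and
assemblage points are expressed on the pool's principal axes. A hull in
`d` dimensions needs at least `d + 1` affinely independent points, so an
assemblage of `n` species uses the leading `d = min(n − 1, 9)` axes; as
the rotation is orthonormal, large assemblages' volumes equal the raw
standardized-space volumes. FRic is undefined below three species, PD
below two; such cells are reported `NA`, excluded from SES maps, and
counted in the run manifest.

**Null model.** One Curveball trade picks two rows uniformly, pools the
columns held by exactly one of them and reallocates the pool uniformly,
preserving both row sums and (trivially) all column sums; the chain's
stationary distribution is uniform over fixed-margin matrices. Replicates
are independent chains from the observed matrix with per-replicate child
seeds (embarrassingly parallel and reproducible), default length
`max(5 · n_species, 1000)` trades — an order-of-magnitude margin over the
O(rows) mixing guidance, and doubling it moves SES by less than 0.1 on
average. The SES denominator uses the sample (n−1) standard deviation
over replicates; the observed value is not pooled into the null
distribution. FRic inside nulls reuses the pooled standardization/PCA
basis — the null varies composition, not the trait space. Checkpointing of
long null runs was considered and dropped: at package problem sizes a full
ensemble takes minutes, so resumability would add state for no benefit.

**Spatial GLS.** The fit profiles the exponential range by REML (ML
optional): an outer one-dimensional optimization over log-range, bounded
to `[1e-3, 10] ×` the maximum pairwise distance, around an inner
generalized least squares solve via the Cholesky factor of the correlation
matrix; the OLS solution is adopted when it beats the best spatial fit.
The fit is nugget-free, matches `nlme::gls(correlation = corExp(...))` to
numerical precision on test fixtures, reduces exactly to OLS at range 0,
and reports t statistics on `n − k` degrees of freedom.

**Modified t-test.** The spatial correlation structure of each variable is
estimated by Moran coefficients in 12 equal-width distance classes
spanning the full range of pairwise distances; the two estimated
structures combine into Dutilleul's effective sample size, clamped to
`(2, n]`, which replaces `n` in the t-test. An earlier variant that
formed classes only up to half the maximum distance discarded real
long-range correlation of smooth fields and left the test
anti-conservative (empirical size ~0.09 at nominal 0.05 in simulation);
full-range classes restore calibration, and both the class count and the
cutoff remain arguments. On white noise the effective sample size is within a few percent
of `n`; on smoothed fields the empirical type-I error stays near nominal
where the classical test rejects several times too often.

**Collinearity screen.** The thresholds (`|r| < 0.7`, VIF `< 5`) are the
field's convention; the *procedure* — pairwise stage first, dropping the
member of the worst pair with the larger mean absolute correlation, then
a VIF stage dropping the largest VIF, ties to the later column — is this
package's construction, chosen to be deterministic and reproducible from
the thresholds alone.

**Group comparisons.** Kruskal–Wallis (tie-corrected, via `stats`) with
pairwise Dunn z tests computed from pooled mean ranks with the tie
correction `Σ(t³−t)/(12(N−1))`; Dunn p-values are Holm-adjusted by default
(Bonferroni and none available) since no particular adjustment is
standard. The compact-letter display uses the insert-and-absorb algorithm
on the adjusted pairwise decisions.

## Problem sizes

Package problem sizes are scaled for interactive use: the default study
is 400 cells and 600 species with 99–999 null replicates (the pipeline
default is 999, matching standard practice; worked examples and the
shipped acceptance script use 99), the demo configuration is a 10 × 10
grid with 15 species and 99 replicates and completes in well under a
minute, and simulation-based checks use 10–500 replicates per property.
The methods contain nothing that limits them to these sizes; the null
ensemble is the cost centre, linear in replicates × cells × hull cost.

## Known limitations

* Planar projected coordinates only; no geodesic support.
* FRic only (no FEve/FDiv/RaoQ) and Faith's PD only (no MPD/MNTD).
* The GLS correlation structure is exponential and nugget-free; other
  variogram families are out of scope.
* The Curveball null controls for richness and occupancy but not for
  spatial structure of occurrences; SES maps inherit that interpretation.
* The modified t-test's distance-class count (12) and half-max cutoff are
  conventional but not canonical; both are configurable arguments.
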