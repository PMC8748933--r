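---
title: "Megafauna legacies in plant defence geography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Megafauna legacies in plant defence geography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antiherbiome)
```

This vignette is the package's account of its science: the models and
rules it implements, the choices made where the design was genuinely
open, what the synthetic study system does and does not emulate, and the
numerical conventions that make results reproducible.

## The analysis in one paragraph

The unit of analysis is the ecoregion. Plant defence traits (wood
density, leaf size, stem spines, leaf spines, latex) are scaled from
species records to ecoregions using occurrence-record abundance as the
weight; extinct megafauna and extant herbivore assemblages are reduced to
per-ecoregion richness, body-mass and diet-structure metrics from
presence grids; climate, soil, fire and hurricane covariates complete the
table. Each trait is regressed on the herbivore and environment
predictors under a fixed selection protocol, the surviving coefficients
are stress-tested against randomizations of the species-by-ecoregion
matrix, the five traits are condensed by PCA and clustered into
"antiherbiomes" (regions of convergent defence strategy), and a
rule-based classifier flags ecoregions that were likely savanna under
Pleistocene megafauna but are forest today, validated against fossil
sites.

## Trait scaling

Species records are summarized per species first: continuous traits by
the arithmetic mean across records, binary traits by the maximum — a
recorded presence of spines or latex outweighs recorded absences, on the
argument that omission is the likelier error and some defences are
plastic. Scaling to ecoregions then follows three distinct paths:

* continuous traits: per grid cell, the community-weighted mean
  `sum(abundance x species value) / sum(abundance)` over species with
  data; the ecoregion value is the unweighted mean over its cells. An
  abundance-weighted cell average is available as a switch
  (`cell_weighting = "abundance"`), since cell weighting is a genuinely
  open choice; the default is unweighted.
* stem spines and latex: presences are the summed abundance of species
  carrying the trait, absences the remaining covered abundance. The
  presence/absence pair is kept as counts — the trait models consume it
  as a binomial response rather than a proportion, so the information in
  the denominator is retained.
* leaf spines: scored on palms only, and with ecoregion abundance
  collapsed to presence/absence before counting, because record counts
  for this smaller species pool are a poor abundance estimate. Ecoregions
  without palms are missing and flagged; downstream they are filled with
  the fitted leaf-spine model's predicted probabilities.

Species lacking a value for a trait are excluded from both numerator and
denominator for that trait — never imputed — which is why each trait has
its own effective species pool. Every summary carries a
`species_coverage` count so representativity can be recomputed.

## Herbivore assemblage metrics

Extinct megafauna are species flagged extinct-in-prehistory with body
mass strictly above 50 kg and a diet at least 90% plants. Extant
herbivores keep the diet threshold, add the requirement of feeding mainly
on aboveground vegetative tissue (dropping frugivores and granivores,
which dominate at small size), and carry no size threshold — there are
too few large extant herbivores for one to be useful; the body-mass
metric carries size information instead. Cell richness is the count of
species present; the ecoregion value is the mean over all of its cells.
Body mass averages the masses of species present per cell, excluding
empty cells (a mean over an empty set is undefined, not zero). Guild
richness uses the same code path with a diet filter, and diet structure
enters the models as the grazer-minus-browser difference because the
per-guild richnesses are strongly collinear with total richness. Species
with unknown diet count toward total richness and no guild. An
allometric density index (`c x mass^b`, Damuth-type `b = -0.75` by
default) is provided purely as a correlation diagnostic against richness;
its coefficients are user-supplied and the index is not used further.

## Disturbance metrics

Fire hotspots are retained when detection confidence is at least 95%,
the date falls in November 2000 – December 2019 inclusive, and at most
10% of land-cover cells within a 1000 m buffer of the hotspot centroid
are agriculture, urban or water. Buffer membership is cell-centre
Euclidean distance — reproducible on a lattice without projection
machinery. Fire frequency is the retained count divided by ecoregion
area times the vegetated land-cover proportion; fire intensity is the
mean radiative power of the retained hotspots. The qualitative exclusion
of ecoregions without large preserved vegetated areas is operationalized
as vegetated proportion below 0.5 (configurable). Hurricane activity is
six-hourly track points per ecoregion area.

## The regression protocol

For each response the candidate predictors are screened pairwise at
|r| ≥ 0.60. Rainfall and soil pH are strongly anticorrelated (the
generator plants r = −0.78), so selection runs twice — once with each —
and the winner is the branch with the lower AIC; the difference is
recorded and flagged when below two points. Selection itself is
bidirectional stepwise AIC from the full model, followed by iterative
removal of the least significant predictor until all p ≤ 0.05. A
quadratic term (body mass squared, forced into the stem-spine model to
allow a mid-size optimum) is kept only together with its linear term,
and the linear term is never pruned first.

Binomial count responses are overdispersed — occurrence records cluster
— so they are fitted with Williams-type heterogeneity weights
`1/(1 + phi (m - 1))`. `phi` is estimated by iterating the Pearson
moment equation and is then, if necessary, increased until the residual
deviance is below the residual degrees of freedom: the weights exist
precisely to enforce that contract. When the plain fit already meets it,
no weighting is applied and the fit is exactly the plain logit — the
reduction property the tests verify. AIC comparisons for binomial models
use the unweighted likelihood so both branches are compared on the same
footing.

Effect sizes are partial correlations recovered from the coefficient
test statistics, `r = t / sqrt(t^2 + df)`, with Fisher-z confidence
intervals on the model's residual df (the alternative of
bootstrap intervals is not implemented; the t-based form is exact for
gaussian models). Per-predictor contributions are general-dominance
values: the increment in fit from adding the predictor, averaged over
all subsets of the other predictors by size, then over sizes. Gaussian
models use plain R² — which makes the contributions sum exactly to the
model R² under an orthonormal design — and binomial models use
McFadden's pseudo-R² at the final Williams weights; the model fit
statistic reported alongside is the adjusted R² (gaussian) or McFadden
(binomial).

Diagnostics: Kolmogorov–Smirnov on standardized residuals against the
standard normal (with the estimated-parameters caveat — the test is
conservative), Breusch–Pagan for heteroscedasticity, and Moran's I on
the ecoregion adjacency graph using the analytic normal approximation
(a permutation Moran test would also be defensible; the analytic form is
the convention here). If Breusch–Pagan rejects at 0.05, coefficient
tests are redone under an HC3 covariance and the pruning loop re-runs.
VIF is computed as `1/(1 - R²_j)` per predictor and asserted ≤ 3.33.
All p-values are two-sided. Finally, the herbivory sign rule: a
significant herbivory coefficient whose sign implies *less* defence
under *more* herbivory (for leaf size, the expected sign is negative) is
not a selective effect and is discarded together with its related
diet-difference term, and selection re-runs without it.

## The randomization test

The null model randomizes the species-abundance-by-ecoregion matrix and
re-estimates the selected model on trait values re-aggregated from each
randomized matrix. The default scheme permutes each species' abundances
across ecoregions independently: it decouples traits from geography
while preserving each species' prevalence and total abundance. Row
permutation and a marginal-preserving swap scheme are available; the
scheme used is recorded in the output. The selected predictor set is
held fixed across replicates — the question is whether the *original
coefficients* could arise with trait geography destroyed, not whether
selection is stable. A coefficient is supported when it falls outside
the 0.05–0.95 band of its null distribution. The band uses symmetric
order statistics (`X_(k)` and `X_(N+1-k)` with `k = floor(0.05 (N+1))`),
the construction whose finite-sample coverage is exactly `2k/(N+1)`
under exchangeability; interpolated quantiles would over-flag by a few
percent at 200 replicates. Replicates whose refit fails are dropped and
counted; more than 5% failures aborts.

## Antiherbiomes

The five ecoregion trait columns (weighted means for the continuous
traits, proportions for the binary ones) are standardized to zero mean
and unit variance; PCA of this matrix is the eigendecomposition of the
trait correlation matrix. The sign convention fixes the first axis to
load positively on stem spines, so positive scores are the
physical-defence pole. All five component axes are passed to clustering
by default (a subset can be chosen); Ward linkage on the scores builds
the tree. The number of clusters is decided against an inertia noise
floor: the median inertia loss of the deepest splits considered
estimates what a structureless split harvests, and partitioning
continues while each split removes at least six times that floor — the
raw loss alone cannot decide (the first split always removes the most),
and in pure-noise matrices no split clears a six-fold bar while planted
structure clears it by an order of magnitude. If even the first split
fails the bar, two clusters are returned with a weak-structure warning.
Cluster indices are arbitrary, so labels are assigned by trait profile:
the cluster combining small leaves with stem spines is SLT, the
highest-wood-density cluster ILW, the large-leaf/latex cluster BCL.
Group contrasts use Kruskal–Wallis followed by pairwise Dunn z tests
(tie-corrected) with Benjamini–Hochberg adjustment; groups with fewer
than two members are excluded and flagged.

## Biome-shift detection

Thresholds are the empirical 0.75 quantiles of megafauna and megagrazer
richness, computed with the nearest-rank (type 1) method — recorded in
the output so the thresholds are reproducible to the species. An
ecoregion is a savanna-to-forest shift when it is currently
forest-dominated, carries an SLT or ILW antiherbiome label (the
defence syndromes of arid nutrient-rich and mesic nutrient-poor
savannas), and meets both richness thresholds; the moist/dry split
follows the biome label. Savanna-biome ecoregions meeting the fauna
criteria are stable savannas. Manual overrides (the analyst's
judgement, e.g. a savanna one species short of the threshold) are
applied last and logged verbatim in the rule trace, which records every
criterion's outcome per ecoregion. A fossil site with past savanna
evidence supports a shift when its present local vegetation is forest
and it lies in, or adjacent to, a shift ecoregion; "vicinity" is
operationalized as shared-boundary adjacency because no distance is
defensible a priori.

## The synthetic study system

The generator builds a lattice world whose planted structure mirrors the
study conditions: about 150 ecoregions (7 insular — insular ecoregions
are excluded from all models, leaving 143), 300 plant species, 126
mammals of which 66 are extinct megafauna with diets browser 22 /
grazer 16 / mixed 15 and 13 unknown. Rainfall and pH are built from
empirically orthonormalized Gaussian factors, so their sample
correlation is the configured −0.78 essentially exactly. Megafauna
richness has a planted two-band geography: the megafauna-rich set — all
savanna-biome ecoregions plus the planted shift set — is sized to sit
exactly above the 0.75 nearest-rank quantile, with grazer richness
placed at 3–6 against a 0–2 background so the derived thresholds land
near the motivating values (14 and 3 species).

Trait geography is planted through an exponential tilt: each species
carries independent standard-normal latent scores per trait, and its
weight in an ecoregion is proportional to
`exp(alpha_s + 0.6 * sum_t u_st D_et)` where `D = X beta + noise` is the
trait's planted linear predictor over standardized covariates. For
normal latent scores this shifts the expected community-weighted mean
linearly in `D`, so the standardized slope of the aggregated trait on a
predictor approaches the planted beta (attenuated slightly by
finite-species and count noise). Occurrence counts are negative binomial
around the tilted weights (record counts are overdispersed; the
dispersion is configurable because no abundance distribution is given
for real occurrence records — an open choice exposed in the
configuration). Antiherbiome structure is planted as trait-centroid
offsets per ecoregion label, with separation 4 (community-mean SD units)
by default so the three planted groups are as cleanly distinct as the
strong group contrasts the analysis is designed around; the residual
ecoregion-level trait noise defaults to `sqrt(max(0.15, 1 - sum(beta^2)))`
so planted slopes are on the standardized scale.

Two deliberate null configurations matter for calibration. With all
betas zero the stepwise protocol's false-selection rate per predictor is
what the pruning threshold implies (about 5–10%). For the randomization
test's calibration, the world must additionally set the residual trait
noise and cluster separation to zero: a world with beta = 0 but nonzero
residual trait geography is *correctly* flagged by the test far more
than 10% of the time, because the test detects any trait–geography
coupling, not only covariate effects. The fully exchangeable null world
is therefore the right reference for the 10% coverage property, and the
distinction is a property of the scientific question, not a test
artefact.

What the generator does not emulate: real spatial autocorrelation
ranges, coastlines or projections (lattice geometry only); taxonomic
error and record duplication in occurrence data; the range-reconstruction
step that produces presence grids (consumed as input); and
secondary-productivity allometry. Passing tests therefore demonstrate
the pipeline's correctness and calibration on data whose generating
process is known — not that the real-world effect estimates are
unbiased under spatially structured confounding.

The cluster-recovery benchmark (`simulate_defence_clusters()`) plants
compact clusters directly in standardized trait space: isotropic
profile noise with unit profile SD truncated at radius 1.35, centroids
at least `separation` profile SDs apart. At separation 3 the clusters
are geometrically disjoint, making "perfect recovery" a well-defined
target rather than a statement about overlap probabilities.

## Numerical conventions and problem sizes

Seeds: every component of the world draws from its own stream derived
from the master seed, so regenerating one component leaves the others
bit-identical. Quantiles for thresholds are nearest-rank (type 1);
randomization bands are symmetric order statistics; ties in the cluster
criterion resolve toward fewer clusters; duplicate flagged predictor
pairs beyond the rainfall/pH pair are reported, not auto-resolved. The
test suite exercises the calibration properties at 500 null worlds x 200
randomization replicates, the effect-recovery property at 100 seeds with
143 model ecoregions, and cluster recovery at 100 seeds x 120
ecoregions; the demonstration pipeline and acceptance script run the
full default world (150 ecoregions x 4 cells, 300 species) with 200
randomization replicates per trait. These sizes make the whole suite
reproducible on a single CPU while keeping every Monte-Carlo proportion
within a couple of percentage points of its asymptote.

## Known limitations

* The Kolmogorov–Smirnov normality check uses estimated parameters and
  is conservative; it is reported, not acted on.
* Moran's I uses binary shared-boundary weights; distance-decay weights
  are not implemented.
* The discard rule for backwards herbivory effects inspects linear
  terms only; a quadratic with no linear effect is left to the analyst.
* Dominance analysis enumerates all predictor subsets and refuses more
  than 12 predictors.
* With re-selection disabled by default, the randomization test
  conditions on the selected formula; enabling per-replicate
  re-selection is available but much slower.
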