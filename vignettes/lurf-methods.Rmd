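---
title: "Land-use random forests for urban NO2: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Land-use random forests for urban NO2: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lurf)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters that matter, what
the synthetic-data generator does and does not emulate, the numerical
choices, and the known limitations.

## 1. The modeling problem

Intra-urban NO2 varies at scales of a few hundred meters, driven by
traffic, development intensity and vegetation. Land-use regression (LUR)
predicts a pollutant surface from buffer-summarized land-use predictors,
but those predictors are heavily correlated, which makes it hard to ask a
*causal-flavored* question: how much NO2 is associated with each land-use
category, and what would a land-use modification do? The land-use random
forest (LURF) approach answers the prediction task with a bagged
regression-tree ensemble (robust to many correlated predictors), ranks
predictors with conditional permutation importance, and probes category
effects by counterfactual feature manipulation.

## 2. Buffer features

For every location, `extract_features()` computes, at twelve radii (100
to 1200 m in 100 m steps):

* areal categories (high/medium/low-intensity development, developed
  open space, trees, shrub, grassland, pasture): category area within the
  buffer disc, in m^2. A raster cell contributes `cell_area x fraction`
  when its **center** falls inside the disc;
* road classes (freeway, primary, secondary, local) and rail: exact
  chord length of segments inside the disc (m);
* freeway vehicle miles traveled, `VMTf = sum(AADT x in-buffer segment
  length)` in vehicle-miles/day -- the standard construction, and
  dimensionally consistent with typical published buffer VMT values;
* housing units and permitted NOx emissions (tons/year) within the disc;
* plus the planar coordinates x, y (smooth spatial trend terms) and
  elevation.

Sixteen buffered categories x 12 radii + 3 point features = 195
predictors. Buffers at the study edge are clipped to the extent without
renormalization (mirrors common practice with real rasters; pad the
extent if you need full discs). If tree cover arrives as separate
deciduous/evergreen/mixed layers they are summed into a single trees
category.

The LULC rasters use 40 m cells. The choice is deliberate: 40 m divides
the 200 m prediction grid with an odd quotient, so prediction points
coincide with LULC cell centers and grid-scale buffer sums can use fast
cumulative-sum disc kernels under *exactly* the same cell-center
inclusion rule as site-scale extraction.

## 3. The forest engine

`fit_forest()` grows CART-style regression trees (variance-reduction
splits, midpoint thresholds) on bootstrap resamples with a random
`mtry`-subset of predictors eligible at each node -- the classical
regression random forest, in place of full conditional-inference trees;
the results of this package flow through importance *ranking* and
range-restricted prediction, both of which this engine preserves, and a
CTree-style engine is a clean extension point. Design constants follow
regression-forest convention at n of order 100: minimum splittable node
size 5, no depth limit (the phase-1 selection forest is the exception,
below). Predictions are the ensemble mean and are restricted to the
training response range; out-of-bag (OOB) predictions give honest error
estimates.

Two implementation contracts are worth stating because tests rely on
them. First, *all* randomness is drawn from R's RNG stream in a
documented order (bootstrap draws, then per-node partial Fisher-Yates
variable sampling, depth-first), so a fixed seed reproduces an ensemble
bit-for-bit, including from an independent reference implementation.
Second, the split criterion is computed with a canonical arithmetic
(candidate rows ordered by value then row index; left sums by sequential
double adds, right sums by sequential subtraction from the node total),
so even mathematically tied candidate splits resolve identically in the
engine and in a naive re-implementation. Ties keep the earlier candidate
in drawn order, then the smaller threshold.

## 4. Conditional permutation importance

`permutation_importance()` measures the mean increase in per-tree OOB
squared error when a predictor is permuted. In conditional mode the
permutation is performed within strata formed by the split points that
covariates correlated with the target (|r| > 0.2, the published default)
use in each tree, which removes the importance inflation that plain
permutation gives to merely-correlated predictors.

Three engineering choices matter with ~200 correlated predictors:

* the phase-1 selection forest uses **shallow trees** (`max_depth = 4`).
  Deep CART trees use dozens of split points, and stratifying ~60 OOB
  observations on them fragments the sample into singletons, where
  permutation is a no-op and importance collapses into noise. Shallow
  trees mirror the early-stopped trees of conditional-inference forests,
  for which the stratification scheme was designed;
* importance is averaged over several permutation repetitions
  (`n_perm = 3` in phase 1) to tame permutation noise on near-zero
  values;
* the freeway-length and freeway-VMT columns are two encodings of one
  physical source (correlation ~0.97). They are excluded from each
  other's conditioning sets: conditioning either on the other leaves only
  the traffic-volume residue and reduces both radius profiles to noise.
  Sibling radii of one category, by contrast, stay in each other's
  strata -- the unique signal of a radius beyond its siblings is exactly
  what discriminates buffer sizes.

## 5. Two-phase model development

Phase 1 (`phase1_select_buffers()`) fits one forest on all 195 columns
and keeps, per category, the radius with the highest conditional
importance (~200 predictors down to 19). All-zero categories are flagged
degenerate and assigned the smallest radius. Phase 2 (`phase2_sweep()`)
fits every (ntree, mtry) combination for each seed on the reduced set
and returns the robust model: the combination minimizing mean OOB RMSE
across seeds, ties broken toward smaller ntree then smaller mtry (the
robustness rule is stated nowhere in the LURF literature; this one is
reproducible and monotone with the intent). The classic study-scale grid
(ntree 500-5000 x mtry 1-8) is available as `classic_sweep_grid()`; the
shipped pipeline default is a reduced desk-scale grid (ntree {200, 500} x
mtry {2, 4, 6}), chosen because the synthetic study at n = 132 gains
nothing measurable from 5000-tree forests.

The LUR baseline (`fit_lur()`) prunes correlated predictors (|r| > 0.7,
keeping the earlier column), runs four stepwise-AIC searches (forward /
both from null, backward / both from full), thins each candidate until
every variance inflation factor is at or below 10, and picks the
candidate with the lowest 6-fold cross-validated RMSE. The stepwise
direction, correlation threshold, VIF ceiling and robust-model rule are
all free parameters of the classical recipe; the defaults above are
common practice and are exposed as arguments rather than guessed
further.

## 6. Surfaces, attribution, scenarios

Seasonal models are evaluated at the 200 m grid cell centers (row-major
from the southwest corner) with features extracted at the selected radii
only, then averaged cellwise into the annual surface. Category
attribution zeroes a category's columns study-wide -- an NO2-neutral
replacement -- and differences the annual surfaces; no rebalancing, per
the counterfactual's definition. Scenario modification is textually
distinct: an areal category changes by signed percentage points *of
buffer area* (`pi r^2` per radius), so a +2 change adds cover even where
there was none; the other areal categories at the same radius are scaled
by a common factor so the within-buffer total is preserved where
possible, and all fractions are clamped to [0, 100]%. On reduced tables
that carry one radius per category the rebalancing pool is the other
areal columns, each in its own buffer's percentage terms. VMTf scenarios
scale the VMT columns by `1 + delta/100` -- a traffic-volume policy, not
a land swap -- and rebalance nothing.

The freeway-length and VMTf columns being near-duplicates, single-column
attributions split the corridor credit between them; the package
therefore also computes the joint zeroing of both columns where the
physical "freeway source" total is wanted (the same aggregation question
arises for published road-category attributions, which is why both forms
are reported).

## 7. Health impacts

`allocate_population()` spreads census-block counts over grid cells in
proportion to polygon-cell overlap area (Sutherland-Hodgman clipping
with a fast path for axis-aligned blocks), conserving totals.
`apply_hif()` implements the log-linear concentration-response
convention `dy = y0 (1 - exp(-beta dC)) Pop` per cell, aggregated over
the study area or the worst NO2 quintile (`worst_quintile_mask()`: the
`ceiling(n/5)` highest-valued cells). The shipped endpoint registry
(asthma exacerbation and missed school days in 4-12 year olds, cough in
7-14, ER visits and respiratory admissions in 65+) uses **synthetic
stand-in coefficients of plausible magnitude**: the original BenMAP
coefficient sets are not printed in the literature this package
miniaturizes, so the registry reproduces structure, age-banding and
sign, not any published effect size. Age-band populations are fixed
fractions of the total (configurable), matching the age-banded endpoint
structure.

## 8. The synthetic city and what it does (not) show

`generate_city()` builds a ~20 x 20 km city: a dense core and secondary
center, two crossing freeways (AADT 90k-140k), primary/secondary/local
road grids, a rail line, ten permitted NOx point sources, eight
NLCD-style areal fraction layers, housing, elevation, and 250 m
census-style block polygons. `simulate_no2_truth()` evaluates the known
generative process: seasonal multiplier x (background + source terms -
sink terms), floored at 1 ppb; line/point terms are exponential
distance-decay kernels (the freeway term AADT-weighted), areal and
housing terms are local disc-density kernels. `sample_sites()` draws 174
summer sites (30% along road corridors at 30-500 m offsets -- the
near-road gradient that identifies a 300 m kernel cannot be resolved by
grid-snapped sites -- 25% in high canopy, the rest uniform) and
re-samples 82 in winter; observations add Gaussian noise (sd 1 ppb, a
plausible passive-sampler error; the true campaign error is not public)
truncated at 0.5 ppb.

The defaults are calibrated once, against the truth surface and site
summaries only: summer site mean ~11 ppb within 4-23, winter ~13 ppb
within 3-29, and an area-average tree association of ~-0.4 ppb, with
eight positive (development, roads, VMTf, rail, housing, emissions) and
three negative (trees, open development, shrub) categories whose
magnitudes follow the ordering familiar from published attribution
tables. Because the generator's stated role is a *recoverable* ground
truth, the layers are designed for identifiability: parks, shrub fields
and street-tree texture vary independently of the urban gradient rather
than mirroring it, and every signal category has a nonzero area-mean
contribution. Housing (and hence population) is suppressed within a few
hundred meters of the freeways -- the familiar empirical pattern that
makes near-road exposure reductions benefit few residents.

What passing tests on this city do **not** show: real atmospheric
transport (no meteorology, chemistry, or terrain channeling), real
spatial autocorrelation structure of measurement error, NLCD
classification error, or transferability between cities. The synthetic
results validate the *machinery* -- extraction geometry, selection,
attribution arithmetic, scenario algebra, health propagation -- not the
atmospheric fidelity of any particular coefficient.

Two quantitative honesty notes from the package's own validation runs.
First, random-forest counterfactual attribution shares credit among
correlated encodings and shrinks magnitudes (the tree attribution is
recovered essentially unbiased; the joint freeway attribution recovers
roughly 40% of its generative value). Second, the phase-1 choice of
buffer radius within a category is intrinsically noisy: the buffer
features of adjacent radii correlate at 0.93-0.96 with a 300 m kernel,
so the importance argmax wanders over several radii from replicate to
replicate. Consumers of radius selections should treat them as
order-of-magnitude statements, not sharp estimates.

## 9. Numerical and interface choices

* Coordinates are planar meters, y north; all buffer math in that CRS.
* Rasters and surfaces travel as ESRI ASCII grid text (plus x,y,value
  CSV); networks, emitters and blocks as GeoJSON; tables as CSV with 17
  significant digits (round-trips faithful to ~1e-15 relative); models
  as a documented JSON structure; configuration as YAML.
* One global pipeline seed derives per-stage seeds by fixed offsets;
  `manifest.json` records stages, seeds and artifact checksums, and a
  rerun with the same configuration reproduces the deterministic
  artifacts bit-for-bit.
* Degenerate inputs: constant responses give single-leaf forests (with a
  warning); constant surfaces give a whole-area worst-quintile mask
  (with a warning); an empty rebalancing pool clamps and warns; metrics
  refuse non-positive observations, naming the record.
* Desk-scale problem sizes used throughout the shipped tests: a 20 x 20
  km city (the published study areas are an order of magnitude larger),
  174/82 sites, 100-500 tree forests, ten replicate campaigns for the
  recovery checks. These sizes were chosen as the smallest at which the
  statistical behavior of interest is visible.

## 10. Known limitations

* The engine is a CART-style forest; full conditional-inference trees
  (significance-test splitting) are not implemented.
* Buffers are discs; ring, inverse-distance-weighted and network-distance
  variants are out of scope.
* Scenarios apply study-wide to a single category; spatially targeted or
  joint multi-category scenarios are not supported.
* Health impacts carry no uncertainty intervals, and economic valuation
  is out of scope.
* The annual average is the two-season mean; no finer temporal structure.
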