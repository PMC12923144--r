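---
title: "Methods: ensemble habitat suitability modelling for marine species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble habitat suitability modelling for marine species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`oceansdm` implements a complete habitat-suitability modelling workflow for
marine species: multi-source occurrence records are harmonised and quality
flagged, the species' habitat is classified along three spatial axes, a
biogeographical range (BR) and a potential range (PR) are constructed, the
presence data are thinned in environmental space, pseudo-absences are drawn
by a habitat-appropriate rule, a ten-algorithm ensemble is fitted under
environmentally blocked cross-validation, and the gated ensemble is
projected onto present and future environments with explicit uncertainty and
range-change products.

The underlying model is a presence/pseudo-absence classification of grid
cells from environmental covariates: each algorithm estimates a map from an
environment vector to a habitat suitability index (HSI) in $[0,1]$, and the
ensemble mean, committee average and coefficient of variation summarise the
retained runs. The key assumption is the niche concept: occurrence
probability is a (smooth) function of the local environment, so records plus
environmental layers identify an environmental envelope that can be
projected in space and time.

## Occurrence harmonisation

Quality flags from heterogeneous sources are collapsed to a ternary scheme:
`1` verified, `0` erroneous, blank unknown. Sources with native binary flags
pass through; multi-flag sources are set to `0` only for geographic
impossibilities (land placement, missing or zero coordinates, implausible
locations), other flags being retained verbatim without implying error;
flag-free sources stay blank. Coordinates are rounded to 4 decimal places
*before* duplicate grouping, so the deduplication key is the rounded
coordinate; rounding is round-half-even (base R `round()`), which differs
from half-up only in the fifth decimal. Records at exactly (0,0) and records
out of coordinate bounds are removed and counted, never raised as errors.

Duplicates group on (taxon, lon, lat, year, month). Missing year/month act
as a distinct key value rather than matching everything — the alternative
(date-blind grouping) would silently merge genuinely distinct records. One
record survives per group: the most complete (has a flag + has a basis of
record), ties broken by source priority then first-seen order, chosen purely
for determinism.

## Habitat classification (three axes)

* **Distance to bottom** maps the habitat vocabulary onto
  pelagic / demersal / benthic.
* **Distance to coast** uses the share $p$ of valid records in the coastal
  (0–800 m) zone: $p \ge 0.9$ neritic, $p \le 0.1$ oceanic, otherwise
  generalist. Both comparisons are inclusive (`>=`/`<=`): the source rule is
  phrased symmetrically as "90% of the data", and an exactly-90% species is
  more defensibly neritic than generalist.
* **Distance to surface**: pelagic species buffer their trait depth range by
  30 m (floored at 0) and take every pelagic zone (epipelagic 0–200 m,
  mesopelagic 200–1000 m, bathypelagic >1000 m) the buffered interval
  overlaps; benthic/demersal species use the benthic depth-zone vocabulary
  (coastal & upper bathyal 0–800, bathyal 800–3500, abyssal 3500–6500, hadal
  >6500 m) without a buffer, falling back to zones holding >10% of records
  when no trait range exists. Zone bounds are treated as closed intervals:
  an interval touching a zone edge counts as overlap, so a buffered maximum
  of exactly 200 m includes the mesopelagic.

## Range construction

All geometry lives on regular lon/lat raster masks. Degree buffers ("1° of
longitude and latitude") are Chebyshev dilations of `round(deg/res)` cells —
literal in degree space, not geodesic, so a 1° buffer covers fewer km of
longitude at high latitude; this matches the buffer's definition in degrees
and is a documented approximation. The "same ocean basin" constraint is the
connected component of the ocean mask containing the pre-buffer range
(8-connectivity flood fill), which both crops land and stops buffers from
jumping basins. Spherical areas use the closed form
$R^2\,\Delta\lambda\,(\sin\varphi_2-\sin\varphi_1)$ with $R = 6371$ km.

With an expert map, BR is the map buffered by 1°, PR by 10°, both
basin-masked. Without one, the range derives from occurrences: bounding box
(degenerate single-record boxes are inflated by one grid cell), spatial
thinning (none up to 1000 records, 20 km up to 5000, 30 km above; greedy
over a seed-shuffled order, so the output provably satisfies the pairwise
minimum-distance property), then province filtering. The retention rule
keeps provinces (and, for benthic/demersal species, depth layers) whose
individual share of records strictly exceeds 3.3%; the alternative
cumulative-tail reading (drop smallest provinces until the dropped mass
reaches 3.3%) is implemented behind `filter_mode = "cumulative"`, but the
per-province reading is the default because the threshold is described as a
per-province occurrence share, the ascending sort being presentational.
Arctic ranges are refined on finer Arctic units at a 0.5% share floor.
Finally, records inside the BR are re-flagged verified, records outside
erroneous; records already flagged erroneous stay erroneous.

## Training data

Unique environments are defined by snapping each layer to the nearest
multiple of its bin size (oxygen 10 mmol m⁻³, temperature 0.05 °C, pH 0.1,
productivity 0.5 mmol m⁻³, salinity 0.1 psu, velocity 0.02 m s⁻¹, depth
5 m); floor-snapping is available behind a flag. Environmental thinning
keeps exactly one record per occupied unique environment (uniformly at
random under the seed), so after thinning the presence count *is* the
species' unique-environment count — this is the quantity that switches the
cross-validation design. For species with an expert map and fewer than 1000
records, pseudo-occurrences are sampled inside the map (restricted to the
species' bathymetric range when known): `min(1000, floor(0.4 × candidate
cells))` cells without replacement, tagged `erm_generated`. Cells holding
real occurrences are excluded so generated points are strictly additional,
and the pooled set is thinned together — the generated points are
themselves presence records and receive no special treatment downstream.

Pseudo-absences are habitat-aware, restricted to the PR and to ocean cells:

* **Pelagic**: the surface range envelope (per-variable 2.5–97.5 percentile
  bounds of presence environments, linear-interpolation percentiles);
  eligible cells have *all* variables outside their interval. That strict
  rule can starve small worlds, so when fewer than `n` cells qualify the
  predicate relaxes to *any* variable outside with a logged warning — the
  strict rule has no defined fallback otherwise.
* **Benthic/demersal**: an exclusion ring — eligible cells lie 80–1000 km
  (haversine, $R = 6371$ km) from the nearest presence.

The pseudo-absence count defaults to the presence count (balanced design).
Case weights give the presence class 0.7 of the total weight (prevalence
as weights, not resampling, so every algorithm sees the same rows).

## Ensemble

Ten algorithm families: GLM (quadratic logistic regression), GAM (`mgcv`
smooths), random forest, artificial neural network (`nnet`, scaled inputs),
flexible discriminant analysis (linear discriminant on quadratic features),
classification tree (`rpart`), gradient boosting (slow-learning depth-3
boosted trees), maximum-entropy-style penalised regression (lasso logistic
on quadratic features via `glmnet`, the computational core of maxent-type
fitting), extreme gradient boosting (`xgboost` defaults), and adaptive
splines (natural-spline logistic regression). Hyperparameters are fixed
sensible settings; a `tuning_hook` callback lets users substitute their own
per-algorithm search without changing the pipeline.

Cross-validation is environmentally blocked when the species occupies more
than 1000 unique environments: for each modelling variable, five quantile
blocks along that variable (built separately within presences and
pseudo-absences so folds stay class-balanced) form one 5-fold scheme, giving
variables × 5 = 30 held-out assignments per algorithm and 300 runs for the
ten algorithms with the six standard variables. With ≤1000 unique
environments the plan is random stratified 5-fold CV repeated 3 times (15
assignments per algorithm), because environmental blocks become too sparse
to guarantee both classes per fold.

Each run is evaluated on its held-out fold: the binarisation threshold
maximises TSS (sensitivity + specificity − 1) over the unique predicted
values, CSI is TP/(TP+FP+FN) at that threshold, and AUC is the
threshold-free Mann–Whitney rank statistic. Runs with held-out TSS
strictly above 0.6 are retained. Ensemble products are the **unweighted**
mean HSI (a weighted mean would systematically favour the
machine-learning members, which score best on the very metrics used for
weighting), the committee average (fraction of retained runs voting
presence at their own TSS-maximising threshold — per-run thresholds keep
the vote consistent with each run's evaluation), and the per-cell
coefficient of variation (0 where the mean is 0). Per-variable calibration
ranges (min/max over training rows) feed the clamping mask: the per-cell
count of variables outside their calibration range, flagging extrapolation.

## Projection and change

Projection evaluates the retained runs on every ocean cell of the target
stack inside the PR. Binarisation uses `>=` at the ensemble-level threshold
(the mean of retained per-run thresholds) — the boundary convention is a
free choice and inclusive is the more common one. Invasion is
future-suitable ∧ present-unsuitable, extinction the reverse; percent area
gained/lost is spherical area relative to the PR area, per the definition of
the modelled area. Richness stacking sums binary maps and normalises by the
maximum; comparison against coarser data uses block-maximum resampling.

## The synthetic world

`make_world()` builds the study conditions every test runs under: a
western continent with a sinuous coast, bathymetry deepening offshore to
abyssal depths, a latitudinal surface-temperature gradient (≈28 °C at the
equator falling towards the poles) with smooth seeded noise, physically
plausible co-gradients for oxygen, pH, salinity, productivity and velocity,
benthic variants attenuated by depth, latitudinal provinces with an Arctic
band subdivided longitudinally, and depth zones cut at 800/3500/6500 m.
Future stacks add spatially uniform per-layer deltas (default +2 °C at the
high-emission end-of-century point, scaled 0.4/0.7/1 across scenarios and
0.5/1 across periods) — uniform by design for analytic tractability.
Species are truncated-Gaussian product niches (the historical trapezoid
response is a documented alternative kernel shape); clean occurrences are
drawn from cells above the suitability cutoff with probability proportional
to suitability, and error records (land points, (0,0) points, exact
duplicates, far strays, missing dates) are injected at stated rates with
ground-truth provenance columns.

What passing tests show — and do not show. The synthetic world has smooth,
low-dimensional gradients, uniform sampling effort inside the range, and
errors of exactly the injected kinds; real occurrence data add taxonomic
confusion, effort bias correlated with coastlines and shipping lanes,
fine-scale habitat structure and label noise that the generator does not
emulate. End-to-end recovery (held-out TSS > 0.6, binarised maps matching
the true range, poleward invasion under uniform warming, ≥90% recovery of
injected geographic errors) therefore validates the machinery, not
real-world predictive skill.

## Numerical choices and problem sizes

Matrices index `[lat, lon]` with latitude ascending; points map to cells by
`floor`, the maximum edge belonging to the last cell. Aggregation is block
means over ocean cells; disaggregation is bilinear between coarse cell
centres after a nearest-neighbour coastal fill, with the fine ocean mask
re-imposed (exact for constant fields, exact to floating tolerance for
bilinear fields away from filled margins). `floor` is used for the 40%
pseudo-occurrence fraction. Thresholds that the source states as "more
than" are strict (`>`); the TSS gate is strict; the coastal rule is
inclusive as discussed. Random draws are all routed through explicit seeds,
restoring the RNG state afterwards, so every pipeline product is
reproducible from (inputs, config, seed).

Test and demonstration runs use worlds of roughly 100–150 × 100–150 cells
at 0.2° with a few hundred occurrence records, which exercises both
cross-validation designs (the 30-assignment environmental design appears
once more than 1000 unique environments are occupied) while keeping a full
ten-algorithm ensemble run to a couple of minutes; these sizes are the
package's choice of demonstration scale, and all rules scale unchanged to
0.05° global grids.

## Known limitations

Geometry is raster-based at the working resolution: range boundaries are
cell-quantised, and vector (polygon) interchange formats are not produced.
Degree buffers are anisotropic in km at high latitude. Only two
environmental strata (surface, benthic) exist, so depth-stratified pelagic
structure is not represented. Cross-basin dispersal is deliberately
excluded by the basin mask. The ensemble's unweighted mean can flatten
sharp niche edges, and committee averages inherit each run's threshold
uncertainty.
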