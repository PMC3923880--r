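---
title: "Climate-change vulnerability assessment on stream networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Climate-change vulnerability assessment on stream networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamvuln)
```

## The problem

Freshwater insects such as dragonflies and damselflies track climate closely:
their larval development is temperature-dependent, their distributions follow
stream networks rather than open landscapes, and their capacity to colonise
new catchments is limited by how far adults disperse. When climate shifts the
suitable environment along a stream network, a species may be harmed in three
distinguishable ways: the conditions inside its current range may move beyond
what it has historically experienced (*exposure*), the total amount and
quality of suitable habitat may shrink (*sensitivity*), and whatever suitable
habitat remains may lie far from where the species currently occurs, so that
persistence depends on long-distance dispersal (*dispersal pressure*).

`streamvuln` implements this three-component vulnerability assessment as a
reusable pipeline over per-subcatchment habitat-suitability surfaces, together
with a synthetic landscape and species generator so every stage can be tested
end-to-end without proprietary continental data. The analysis grain is the
*subcatchment*: the smallest spatial unit of a stream network, carrying a
seven-factor environmental description (three temperature, three
precipitation, one flow variable).

## Habitat suitability

Suitability surfaces come from a pluggable scorer behind a fixed interface:
any object with a `predict` method mapping a per-subcatchment factor table to
`[0, 1]` can stand in. The built-in scorer (`fit_scorer()`) is a binomial GLM
with a linear and a quadratic term per standardized factor — a Gaussian niche
on the logit scale, fitted by maximum likelihood on presence/pseudo-absence
labels. This replaces multi-algorithm ensembles deliberately: the assessment
framework being provided here is downstream of model choice, and a
well-specified single scorer keeps the pipeline fast, deterministic and
testable. The surrounding machinery is faithful to common SDM practice:

* **Pseudo-absences** (`select_pseudo_absences()`) are taken from background
  localities where *other* species were collected within 300 km of a presence
  (excluding occupied subcatchments), supplemented by random localities to a
  fixed total. The radius is plain Euclidean distance — at model-building time
  no dispersal cost surface exists yet.
* **Evaluation** (`evaluate_predictions()`) reports AUC (midrank formula,
  ties counted half) and the True Skill Statistic, maximized over every
  distinct predicted score; the smallest maximizing score is kept as the
  binary threshold τ. A surface value counts as habitat iff it is **≥ τ**
  (inclusive boundary, so τ itself remains meaningful).
* **Ensembling** (`fit_ensemble()`) fits seeded replicates on 70/30 splits
  and weights each replicate by its held-out TSS (truncated at zero). The
  default is 5 replicates, configurable to 10; the reduced default keeps the
  synthetic study quick without changing any interface. τ is chosen once on
  the ensemble surface over all training localities rather than per
  replicate — a single species-level threshold is what the sensitivity stage
  needs, and thresholding members individually would leave the ensemble
  surface without a defined cut.
* **Clamping** (`clamp_surface()`) guards against extrapolation: a
  subcatchment where **more than one** factor lies outside the training range
  has its suitability multiplied by a penalty (default 0, a hard clamp).
  Tolerating a single out-of-range factor permits modest gap-filling while
  blocking multi-factor extrapolation; the penalty and the tolerated count
  are both configuration.

### Parameter recovery

Because the synthetic species are generated from known Gaussian niches, the
scorer can be audited against truth. With strong signal (peak occupancy 0.95,
tolerances at half the factor SD) the fitted quadratic recovers the niche
optima to about half a tolerance and separates presences from absences with
held-out AUC near 1. This is a well-specified-model check, not a claim about
messy real data: real occurrence records carry detection noise, taxonomic
error and correlated sampling effort far beyond what the generator emulates.

## Exposure

For each species, exposure under a future scenario is the mean over its
currently suitable subcatchments of `|future − current| / SD`, per factor.
The SD basis is, by default, the spatial SD of current values across the
species' suitable habitat — a proxy for the variation the species already
tolerates. (The conceptually preferable basis, inter-annual variability,
needs a time series the data model does not carry; externally supplied SDs
are accepted through `sd_mode = "supplied"`.) Shifts count in either
direction — a cooling departure is as much a departure as a warming one.

Exposure is assessed on five measures — temperature mean and seasonality,
precipitation mean and seasonality, and annual flow — with the wet/dry
quarter precipitation pair averaged into the precipitation-mean measure (the
mapping is configuration). A species is *exposed* if any measure shifts by
more than 2 SD, if two or more measures shift by more than 1 SD, or if at
least 10% of its suitable subcatchments lie within 1 m of sea level
("multiple factors" is read minimally as ≥ 2). Every fired rule is recorded,
so reports show *why* a species is exposed.

## Sensitivity

Sensitivity compares thresholded suitability totals. Values below τ are
zeroed, both surfaces are summed, and

$$S = \frac{\sum HS_{current} - \sum HS_{future}}{\sum HS_{future}}.$$

S = 0 means no net change; S = 1 means future suitability halved; S < 0 means
expansion. Species with **S strictly above 1** are flagged sensitive. A
species whose future total is zero (all habitat lost) would have infinite S;
it is reported instead with `S = NA`, a degenerate flag and `sensitive =
TRUE`, keeping report tables finite and sortable. Negative S is kept raw in
reports; it is clamped to zero only inside priority maps, where an expanding
species should not subtract conservation value.

## Dispersal pressure

Dispersal enters through cost-weighted distances and a kernel:

* `build_cost_surface()` prices each grid cell: land 1, open water 2 by
  default (dragonflies do cross water, reluctantly), 100 under the *barrier*
  scenario, which makes the sea effectively impassable.
* `cost_distance()` runs Dijkstra's algorithm (via igraph) over the
  8-connected grid graph, each step costing
  `cell_size × mean(end-point costs) × √2-for-diagonals`, minimized over all
  of a species' occurrence cells. Each subcatchment reads its distance at the
  member cell nearest its centroid; occupied subcatchments are at distance 0.
* `kernel_value()` converts distance to dispersal probability with a
  four-parameter logistic `k(d) = c + (a − c)/(1 + (d/d_0)^b)`, defaults
  a = 1, c = 0. The inflection d₀ is 300 km under current conditions and
  630 / 1080 km for the 2055 / 2085 horizons — an expansion allowance of
  15 km yr⁻¹ between horizons. Steepness b = 4 keeps `k ≈ 0.99` at `0.3 d₀`
  and `k ≈ 0.06` at `2 d₀`: near-free movement inside the threshold and a
  rapid, but not cliff-edged, cutoff beyond it. b is configuration; nothing
  else in the pipeline depends on its exact value.

Dispersal pressure is scored in two parts, totalling at most 5 points:

1. **Habitat shift (0–2).** Distances from records to all currently suitable
   subcatchments are compared with distances to all future-suitable
   subcatchments by a one-sided Wilcoxon rank-sum test (midranks,
   tie-corrected variance; the one-sided p additionally carries a continuity
   correction, which tracks the exact permutation p closely at small n).
   Score 0 if the future is not significantly farther (z < 1.96), 1 if
   significant (z < 3), 2 beyond three SDs. An empty future-suitable set
   scores 2 with a sentinel infinite z.
2. **Threshold sweep (0–3).** The kernel inflection is swept over 30 equally
   spaced levels from 300 km up to the scenario threshold, S recomputed at
   each level, and S regressed on ln(d₀) by OLS within each tercile of 10
   levels (fitting 10 points per tercile; sweeping on the linear distance
   scale — log spacing is available as configuration). A species scores 3,
   2 or 1 if the slope is ≤ −1 in the high, medium or low tercile
   respectively, 0 otherwise. Since S can only fall as d₀ grows, slopes are
   non-positive; the cut's magnitude of 1 mirrors the sensitivity cut, so a
   scoring tercile is one across which habitat effectively halves. Levels
   where the future total hits zero make their tercile maximally steep
   (−Inf); if every level is degenerate the species scores 3 with a flag.

A total of **3 or more of the 5 points** flags the species as pressured.

## Categories, barrier scenario, priorities

The three binary flags combine into the standard categories: all three →
**Category 1** (highly vulnerable); exposed + sensitive → **2** (declines in
place); exposed + pressured → **3** (can persist by dispersing); sensitive +
pressured → **4** (declines and shifts before exposure registers). The three
remaining single-flag combinations and the all-clear case map to **LC**; the
raw flags are kept in every report so users can re-bin.

The *barrier* scenario reruns the distance-dependent stages with water cost
100× and compares recomputed S values and categories (`barrier_impact()`);
exposure also re-derives, since the current habitat mask itself depends on
dispersal-constrained surfaces. Conservation priorities
(`conservation_priority()`) score each subcatchment as
`Σ max(S, 0) × HS` over Category 1–2 species, suitability below each species'
τ zeroed — high scores mark subcatchments that are suitable for many
vulnerable species or for species with little habitat left elsewhere.

## The synthetic landscape generator

`generate_landscape()` builds a gridded land/sea world: a smoothed Gaussian
random field becomes elevation, its lowest fraction becomes open water, and
coastal land cells are forced low so the sea-level exposure rule is
exercisable. Subcatchments are grown by seeded region growing from random
land cells — contiguous, irregular units resembling catchments without any
hydrological modelling. Connected land components are labelled (`mainland`,
`island1`, …), which is what makes barrier scenarios meaningful.

`generate_scenarios()` lays a mean + spatial gradient + Gaussian noise
baseline per factor (temperature trending north–south, precipitation mostly
east–west, so factors decorrelate enough to be separately estimable) and adds
per-subcatchment sampled anomalies for each future horizon: roughly +1.8 °C
by 2055 and +3.6 °C by 2085 with drying precipitation and declining flow,
magnitudes chosen to resemble medium-to-high emissions trajectories. Only the
additive anomaly structure of downscaled projections is emulated — no
general-circulation-model behaviour, no elevational downscaling, no
hydrological routing.

`generate_species_truth()` draws per-factor niche optima inside the realized
10–90% range of current conditions and tolerances of 0.4–1.0 × the factor's
spatial SD — regionally restricted ranges rather than continental ones, which
is typical of the freshwater insect faunas this framework addresses and is
what makes dispersal constraints consequential at all. Occupancy is the
product of per-factor Gaussians scaled to the species' peak probability.
`sample_occurrences()` then draws records with probability proportional to
occupancy times a spatial bias factor `exp(−bias_strength · d / d_scale)`
toward a few random "settlement" centers (`d_scale` the landscape diagonal),
emulating collection effort concentrated near towns and roads;
`bias_strength = 0` is exactly unbiased. Record year, life stage and sex are
drawn uniformly — those fields exist so that readers and filters can be
tested, not to carry signal.

### Scale

The default synthetic study uses a 50 × 50 grid of 25 km cells (a 1250 km
square), 150 subcatchments, 30 species and two future horizons. The cell size
is deliberately coarse: with 300–1080 km kernel thresholds, a landscape must
span on the order of a thousand kilometres before dispersal constraints bite,
and 2500 cells keep a full run — ensemble fits, two cost surfaces, 60
least-cost distance fields, threshold sweeps, a barrier rerun and priority
maps — under a minute on a single core. Pseudo-absence totals are scaled to
the synthetic landscape (default 300) for the same reason. Everything scales
up through `vuln_config()`.

## Numerical and degenerate-input conventions

* All randomness flows from named seeds; every generator and the pipeline are
  bit-reproducible, and report files embed the config hash and seed.
* Binary threshold: suitable iff `HS ≥ τ`. Sensitivity flag: `S > 1` strict.
  Sea-level rule: fraction `≥ 0.10` inclusive. Exposure SD rules: strict.
* Zero-variance factors are dropped from scorer fits with a warning; a zero
  SD basis in exposure is an explicit error naming the factor.
* Unreachable subcatchments carry infinite distance; the kernel maps them to
  suitability 0 regardless of its lower asymptote.
* A species with both suitability totals zero is an explicit error ("never
  modelled as present"); the pipeline instead drops species whose *current*
  dispersal-constrained habitat is empty, recording them as excluded — the
  assessment is undefined for them, exactly as species with unstable
  projections are removed from real studies.
* GLM separation warnings in near-perfectly separable fits are suppressed;
  the fitted probabilities are used as scores, for which separation is
  benign.

## Known limitations

* The built-in scorer is logit-quadratic: multimodal or strongly skewed
  niches need an external scorer plugged into the same interface.
* The exposure SD basis is spatial, not temporal (see above).
* The synthetic generator does not emulate detection error, temporal biases
  in records, spatial autocorrelation of residuals, or hydrological
  connectivity along networks — passing tests demonstrate the pipeline's
  arithmetic and contracts, not realism of any particular ecological
  conclusion.
* Priority maps are additive weighted sums; no complementarity or
  reserve-design optimization is attempted.
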