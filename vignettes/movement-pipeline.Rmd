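---
title: "Modeling daily top-predator movement: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling daily top-predator movement: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

predmove quantifies how intrinsic traits, anthropogenic disturbance, refuge
cover and prey type jointly shape the daily movement of GPS-collared top
predators (the motivating system is wolves in heavily anthropised
landscapes). This vignette documents the models, the tunable parameters, the
synthetic-data generator used for validation, and the design decisions taken
where the methodology left genuine choices.

## The daily movement metrics

Telemetry arrives as 2-h GPS fixes per individual in a planar metric
coordinate system (users of real data must project first; all package
geometry is Euclidean km). Fixes are segmented into *daily tracks* spanning
16:00 to 14:00 of the following day, the window between the population's
main resting periods; fixes in the 14:00-16:00 gap belong to no track. A
day offers at most 12 locations; a track is kept only when more than 90% of
them are present, i.e. at most one missing fix. Missing intermediate fixes
are bridged by a single longer step (no interpolation is attempted, the
minimal assumption under a one-missing-fix cap).

Three metrics summarise each track:

* **daily distance** — the sum of Euclidean step lengths (km);
* **net displacement** — straight-line distance from first to last fix (km);
* **straightness index** — net displacement / daily distance in [0, 1].
  When the daily distance is exactly zero the index is 0/0 and recorded as
  undefined rather than imputed; such rows are excluded from the
  straightness model only.

Summary tables report mean, median, SD, min, max, Q1, Q3 and IQR; quartiles
use linear interpolation (R quantile type 7), stated here because IQR values
are convention-dependent.

## Influence areas and covariates

Each daily track is buffered by 1 km — on the order of the mean 2-h step
length — and covariates are averaged inside this *influence area*:

* **Human population / settlement density** — a quartic-kernel density
  surface over settlement points (weighted by population, and unweighted for
  settlement density), bandwidth 1 km by default. The bandwidth is
  configurable because the source methodology names the tool but not its
  bandwidth; an exact point-count variant is provided for settlement
  density as the unweighted alternative.
* **Primary/secondary road density** — road length clipped against the
  exact buffer divided by its area (km/km²). Clipping is evaluated on a 1-m
  densification of the road lines, with error far below any reported digit.
* **Terrain ruggedness (TRI)** — Riley's index: per cell, the root of summed
  squared elevation differences to the eight neighbours; averaged over the
  influence area.
* **Refuge metrics** — on a 10-m binary refuge raster clipped to the
  influence area: percentage cover, patch density, mean patch size, mean
  patch cohesion, and mean fractal dimension index
  (FDI = 2 ln(0.25 P) / ln A in cell units; a square is exactly 1,
  single-cell patches are assigned 1). Patches use 8-connectivity (the
  common FRAGSTATS default; configurable). Cohesion uses the FRAGSTATS
  patch-cohesion formula reported on [0, 1] (the conventional value divided
  by 100). A published description of the index as ranging from −1 to 1
  does not correspond to any standard cohesion formula; we keep the
  standard [0, 1] form and note the discrepancy rather than rescaling.
  Patches are clipped to the influence area before metric computation
  (locality of the daily experience); whole-patch inclusion was the
  alternative and can be obtained by buffering first.

Influence areas are represented as raster masks on the landscape grid (a
cell belongs when its centre is within the radius of the track polyline);
at 10 m the area error of a 1-km disk is below 0.1%.

The five refuge metrics are strongly collinear, so models use the first two
components of a correlation-matrix PCA. Signs are fixed for
reproducibility: dimension 1 loads positively on cover (extensive, cohesive
refuge scores high), dimension 2 positively on FDI (complex natural patch
shapes score high).

## The Bayesian hierarchical models

Each of the three metrics gets a single a-priori model — no model selection
— with fixed effects for age, sex, social status, reproductive period
(mating Feb–Apr, breeding May–Oct, nonreproductive Nov–Jan), diet category,
population and settlement density, both road densities, TRI and the two
refuge dimensions; interactions sex×period, status×period,
population×settlement, each road class × each refuge dimension, and
refuge1×refuge2; and random intercepts for the individual and for the
1×1 km grid cell containing the track's mid-coordinates (fine-scale spatial
effects). All continuous predictors are standardised; interaction columns
are products of the standardised parents.

Daily distance and net displacement are square-root transformed and fitted
with Gaussian errors. Straightness uses a zero-inflated Beta: zeros occur
with probability π, positive values follow Beta(μφ, (1−μ)φ) with a logit
link on μ. Exact 1s (excluded by the Beta support) are compressed by
y′ = (y(n−1)+0.5)/n applied to boundary values only — the minimal
boundary-handling consistent with reporting a maximum just below 1.

Priors are Normal(0, 10) for the intercept, Normal(0, 1) for slopes,
half-Student-t(3, 0, 2.5) for the three SDs and half-Student-t(3, 0, 10)
for φ. Sampling runs in JAGS; the default configuration is 4 chains × 4,000
iterations with 2,000 warmup. Package tests and the bundled demo use 2
chains × 1,500 with 500 warmup, which converges (R-hat < 1.05 throughout;
the operational convergence rule is R-hat < 1.01 at the full configuration,
since "R-hat ≈ 1" is not testable verbatim). Random slopes are deliberately
absent: the design specifies random intercepts only.

Temporal autocorrelation between consecutive daily tracks is handled by
stratified subsampling rather than autoregressive terms: within every
individual×month stratum, floor(2n/3) tracks are kept plus one with
probability equal to the fractional remainder — the expected kept fraction
is exactly 2/3, and a stratum of 3 always keeps 2.

## Inference and variable importance

* **Probability of Direction**: share of posterior draws on the dominant
  side of zero, in [0.5, 1]; PD > 0.9 flags a credible direction, and a
  predictor is called significant when its 95% equal-tailed interval
  excludes zero.
* **Pseudo-R²**: squared Pearson correlation between observed responses and
  median posterior predictions. Whether predictions should be compared on
  the natural or square-root scale is not fixed by the methodology; both are
  exposed and the natural scale is the default.
* **Variance partitioning**: each term is neutralised in turn — continuous
  terms at their mean (interactions recomputed from the neutralised value,
  keeping the design internally consistent, since main effects and
  interactions are reported as separate contributors), categorical terms
  fixed to each level with drops averaged (unweighted mean by default;
  frequency-weighted values are also reported), interaction terms fixed at
  their training-mean column values, random effects replaced by a novel
  level whose effect is the population level — and the drop in pseudo-R²
  is expressed as a percentage of the baseline. Small negative drops can
  occur by chance; they are floored at zero for percentages while the raw
  values are retained. Group totals (intrinsic, anthropogenic, trophic,
  landscape, refuge, random) follow a configurable term→group map.

## Diagnostics

Residual ACF is computed within individuals at daily lags, pairing only
residuals exactly k days apart so subsampling gaps break lag chains.
Moran's I uses inverse-distance weights with a 5-km cutoff by default (the
test is standard; the weight choice is ours and configurable). For fitted
models, Moran's I is evaluated on residuals averaged per grid cell at cell
centres: with repeated tracks per cell, per-record testing at coincident
coordinates would mostly measure the within-cell shrinkage of the cell
random effect. Posterior predictive checks compare observed mean, SD and
(for straightness) zero fraction against replicate simulations from
posterior draws.

## The synthetic-data generator

Real telemetry of this kind is legally protected, so validation runs on
synthetic data with known ground truth. The generator is first-class,
tested code, not a fixture.

**Landscape.** A planar rectangle (default 20×20 km at 10-m rasters)
carrying: a refuge raster from thresholded smoothed Gaussian noise (the
threshold is the quantile matching the target cover, default 50%, with a
300-m patchiness scale so patch size and shape span both PCA dimensions); a
smooth elevation field (600 m relief); uniform settlement points at 3/km²
with heavy-tailed log-normal populations; and straight-chord roads
accumulated to 0.5 (primary) and 3 (secondary) km/km² — totalling the
~3.5 km/km² road density and ~3 settlements/km² characteristic of the
motivating study region. All layers are deterministic functions of the
seed.

**Tracks.** Individuals (default 26, tracked 52–397 days, attribute
frequencies matching the field sample) perform a correlated random walk
with a home-centre attraction (scale 4 km, set once so that simulated
straightness ≈ 0.45 and net displacements are a few km, the realistic
range). Deployments are staggered uniformly over a year, as in multi-year
collaring campaigns, and each walk runs 20 unrecorded burn-in days first:
without both, time-since-deployment aliases the reproductive period and
the distance-from-home transient, and period coefficients absorb a
spurious trend. Home sites are rejection-sampled so the local fixed-effect linear
predictor is not suppressed below ~1.5 √km — territories do not establish
in the most heavily disturbed cells, mirroring den-site selection; this
conditions only on covariates and therefore leaves effect recovery
unbiased. Movement is controlled at the day level, matching the daily
aggregation of the models: each day's expected √(daily distance) equals
the true linear predictor — fixed effects on standardised local covariate
fields at the day's start, plus individual and grid-cell intercepts — a
Gaussian deviate sets the day's path length, and a Dirichlet split
distributes it over the 11 within-day steps, so summed step lengths
reproduce it exactly and the generative model coincides with the fitted
one. Steps that would leave the landscape are re-aimed, never shortened.
Fixes are dropped independently at the missingness rate (the simplest
mechanism consistent with the completeness filter). The default effect
structure (`default_truth()`) encodes the qualitative findings the package
is designed to detect: movement reduced by settlement/population density
and their interaction, by roads and rugged terrain, increased by extensive
cohesive refuge which also buffers road effects, and reduced for
livestock-feeding individuals; with an intercept of 2.9 √km this yields
daily distances around 7–9 km.

The generator's covariate fields stand in for the extraction pipeline
(kernel settlement surfaces, disk road densities, aggregated TRI, and two
refuge fields standing in for the PCA axes). Fields are standardised
landscape-wide by a rank-based inverse-normal transform: the raw surfaces
(road and settlement density above all) are strongly heavy-tailed, and
plain z-scoring would let a handful of extreme cells dominate the linear
predictor and push expected √distances below zero, where the Gaussian
model on the square-root scale is not a coherent generative law. Days
whose drawn √distance still falls below 0.1 √km are floored there (10-m
resting days; a few percent under the default effect sizes). Recovery
tests fit
models on the simulator's emitted day table with `standardize = FALSE` —
re-standardising by the visited-sample SD would silently rescale the true
coefficients.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: behavioural states (denning, territorial
patrolling, road-crossing decisions), temporal activity cycles, collar
fix-quality covariates, autocorrelated missingness, and real land-use
geometry. It validates the statistical machinery, not ecological realism.

## Numerical choices and problem sizes

Degenerate inputs are explicit failures rather than silent coercions:
zero-variance predictors, unknown factor levels, empty metric tables,
constant residuals in Moran's I. Draws of √distance below 0.1 are clamped
(a 10-m day; the paper-scale minimum is 20 m), affecting a negligible
fraction of days. FDI values outside [1, 2] on pathological discrete
shapes are clipped with a reported count. Reference validation sizes were
chosen to estimate each quantity with comfortable precision at desk scale:
1,000 random tracks for metric-oracle equivalence, 200 random 20×20
rasters for landscape-metric oracles, 5 replicates of 20 individuals × 150
days for Gaussian recovery, n = 2,000 for zero-inflated Beta recovery, and
200 replicates for diagnostic calibration.

## Interfaces

The package is an R API; `run_pipeline()` orchestrates the full analysis
from a single seeded configuration and writes every artifact (metrics,
covariates, PCA, fits, PD tables, variance partitions, diagnostics, and a
manifest logging every record-count change) as plain-text CSV/JSON. Rasters
are exchanged as Esri ASCII grids and vector layers as GeoJSON, text
formats readable by any GIS. Posterior draws are serialised as CSV plus a
JSON summary.
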