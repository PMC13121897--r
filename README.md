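# predmove

Daily movement analysis for GPS-collared top predators in human-dominated
landscapes.

Wide-ranging carnivores such as wolves adjust how far and how directly they
travel each day in response to human settlement and population density, road
networks, terrain, the type of prey they exploit, and the extent and spatial
configuration of vegetation cover that shelters them. `predmove` implements
the full analysis chain used to quantify these joint effects from 2-h GPS
telemetry:

1. **Daily tracks and metrics.** Fixes are segmented into 16:00–14:00 daily
   tracks (at most 12 locations; tracks with more than one missing fix are
   discarded) and summarised by three metrics: daily distance
   `D = Σ step lengths`, net displacement `N = ‖x_last − x_first‖`, and the
   straightness index `S = N / D ∈ [0, 1]`.
2. **Influence-area covariates.** A 1-km buffer around each track is
   intersected with landscape layers: quartic-kernel settlement/population
   density surfaces, primary/secondary road densities (km/km²), Riley's
   terrain ruggedness index, and five refuge-patch metrics (cover %, patch
   density, mean patch size, FRAGSTATS patch cohesion, fractal dimension
   index), which a PCA reduces to two refuge dimensions.
3. **Bayesian hierarchical models (JAGS).** For each metric, a single
   a-priori model with the full fixed-effect and interaction structure and
   random intercepts for the individual and the 1×1 km grid cell:
   `√D ~ Normal(Xβ + u_ind + v_cell, σ)` for the distances, and a
   zero-inflated Beta `S = 0 w.p. π; S | S>0 ~ Beta(μφ, (1−μ)φ)`,
   `logit(μ) = Xβ + u + v` for straightness. Priors: `β₀ ~ N(0,10)`,
   `β ~ N(0,1)` on standardised predictors.
4. **Inference.** Probability of Direction (PD), credible-interval
   significance, marginal-effect grids, and variance partitioning: the drop
   in predictive pseudo-R² (squared correlation of observed responses with
   median posterior predictions) when each predictor is neutralised, as a
   percentage of the baseline.
5. **Diagnostics.** R-hat, within-individual residual ACF over daily lags,
   Moran's I of spatial residuals, posterior predictive checks.
6. **Synthetic ground truth.** Because telemetry of protected predators is
   typically not shareable, the package ships a seeded landscape and
   correlated-random-walk simulator whose daily distances follow the exact
   model being fitted with known coefficients, so the whole chain is
   validated by parameter recovery.

## Worked example

```r
library(predmove)

land  <- generate_landscape(landscape_config(extent_km = c(10, 10), seed = 7))
sim   <- sim_config(n_individuals = 4, days_per_individual = 30,
                    missingness_rate = 0.03, seed = 3)
tracks <- simulate_tracks(land, sim, default_truth())

dt  <- filter_complete(segment_days(tracks$fixes))
mm  <- track_metrics(dt)
summarize_metrics(mm)
#>                metric      min     q1 median   mean      q3    max     sd    iqr
#> 1   daily_distance_km 0.010752 3.6888 7.2762 8.4591 12.0889 27.991 6.3405 8.4001
#> 2 net_displacement_km 0.007892 1.2977 2.3902 2.4901  3.5360  8.405 1.6473 2.2383
#> 3        straightness 0.026790 0.2195 0.3533 0.4144  0.6369  0.906 0.2448 0.4174
```

The simulated population travels a mean of ~8.5 km per day with a mean
straightness of 0.41 — daily paths are fairly tortuous, as expected for a
territory-holding predator commuting around a home centre. Covariates,
refuge PCA and a model fit then follow:

```r
cov <- extract_covariates(dt, land, tracks$attributes)
cov <- add_refuge_dims(cov)            # appends refuge_dim1 / refuge_dim2
rec <- merge(cov, mm[, c("track_id", "daily_distance_km")], by = "track_id")
rec <- subsample_two_thirds(rec, seed = 1)

fit <- fit_movement_model(rec, "daily_distance",
                          chains = 2, iter = 1500, warmup = 500)
probability_of_direction(fit)          # PD, 95% CI, significance per term
variance_partition(fit)                # % of pseudo-R² per term and group
diagnose_fit(fit)                      # rhat, residual ACF, Moran's I, PPC
```

`run_pipeline(run_config(...), outdir = "out")` performs all stages in one
seeded call and writes every table (metrics, covariates, PCA loadings,
draws, PD, variance partitions, diagnostics, manifest) as plain-text
CSV/JSON.

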