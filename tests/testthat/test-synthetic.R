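# Synthetic landscape generator and GPS-track simulator.

test_that("landscape generation hits its targets and is deterministic", {
  cfg <- landscape_config(extent_km = c(10, 10), refuge_target_cover = 0.5,
                          refuge_patchiness_m = 200, seed = 21)
  ls1 <- generate_landscape(cfg)
  ls2 <- generate_landscape(cfg)
  expect_identical(ls1$refuge, ls2$refuge)
  expect_identical(ls1$settlements, ls2$settlements)
  expect_identical(ls1$roads, ls2$roads)

  expect_gte(mean(ls1$refuge), 0.47)
  expect_lte(mean(ls1$refuge), 0.53)

  rl <- road_lengths(ls1$roads) / prod(ls1$extent_km)
  expect_equal(unname(rl["primary"]), 0.5, tolerance = 0.1)
  expect_equal(unname(rl["secondary"]), 3, tolerance = 0.1)

  expect_true(all(ls1$settlements$population >= 1))
  expect_true(all(ls1$settlements$population == round(ls1$settlements$population)))

  empty <- generate_landscape(landscape_config(extent_km = c(2, 2),
                                               refuge_target_cover = 0, seed = 1))
  expect_true(all(empty$refuge == 0))
})

test_that("invalid landscape configurations fail loudly", {
  expect_error(landscape_config(extent_km = c(-1, 5)), "positive")
  expect_error(landscape_config(refuge_target_cover = 1.2), "\\[0, 1\\]")
  expect_error(landscape_config(extent_km = c(5, 5), raster_resolution_m = 333),
               "divide")
  expect_error(landscape_config(road_km_per_km2 = c(primary = -1, secondary = 0)),
               "nonnegative")
})

test_that("landscape round-trips through plain-text formats", {
  ls1 <- generate_landscape(landscape_config(extent_km = c(2, 2), seed = 5))
  d <- withr::local_tempdir()
  paths <- write_landscape(ls1, d)
  rt <- read_ascii_grid(paths["refuge"])
  expect_equal(rt$matrix, ls1$refuge, ignore_attr = TRUE)
  expect_equal(rt$cellsize, ls1$res_km)
  gj <- jsonlite::read_json(paths[["settlements"]])
  expect_equal(length(gj$features), nrow(ls1$settlements))
})

test_that("simulated days have exactly 12 fixes without missingness", {
  ls1 <- generate_landscape(landscape_config(extent_km = c(8, 8), seed = 3))
  tr <- simulate_tracks(ls1, sim_config(n_individuals = 3, days_per_individual = 20,
                                        missingness_rate = 0, seed = 4),
                        default_truth())
  dt <- segment_days(tr$fixes)
  expect_true(all(dt$tracks$n_observed == 12L))
  expect_equal(nrow(dt$tracks), nrow(tr$days))

  # positions stay inside the extent
  expect_true(all(tr$fixes$x_km >= 0 & tr$fixes$x_km <= 8))
  expect_true(all(tr$fixes$y_km >= 0 & tr$fixes$y_km <= 8))

  # determinism
  tr2 <- simulate_tracks(ls1, sim_config(n_individuals = 3, days_per_individual = 20,
                                         missingness_rate = 0, seed = 4),
                         default_truth())
  expect_identical(tr$fixes, tr2$fixes)
  expect_identical(tr$days, tr2$days)
})

test_that("daily distances computed from fixes equal the simulator's truth", {
  ls1 <- generate_landscape(landscape_config(extent_km = c(10, 10), seed = 7))
  tr <- simulate_tracks(ls1, sim_config(n_individuals = 4, days_per_individual = 30,
                                        missingness_rate = 0, seed = 3),
                        default_truth())
  mm <- track_metrics(filter_complete(segment_days(tr$fixes)))
  j <- merge(mm, tr$days, by = c("individual_id", "track_date"))
  expect_equal(nrow(j), nrow(tr$days))
  expect_lt(max(abs(j$daily_distance_km - j$daily_distance)), 1e-9)
})

test_that("a null model yields constant expected sqrt distance", {
  ls1 <- generate_landscape(landscape_config(extent_km = c(10, 10), seed = 7))
  tt <- truth_table(beta = c("(Intercept)" = 2.5), sigma_individual = 0,
                    sigma_cell = 0, sigma_resid = 0.6)
  tr <- simulate_tracks(ls1, sim_config(n_individuals = 6, days_per_individual = 120,
                                        missingness_rate = 0, seed = 6), tt)
  per_ind <- tapply(tr$days$sqrt_daily_distance, tr$days$individual_id, mean)
  # Monte-Carlo error of a mean of 120 draws with SD 0.6 is ~0.055
  expect_true(all(abs(per_ind - 2.5) < 0.2))
})

test_that("a known settlement effect is recovered by OLS on simulator output", {
  ls1 <- generate_landscape(landscape_config(extent_km = c(20, 20), seed = 11))
  tt <- truth_table(beta = c("(Intercept)" = 2.9, settlement_density = -0.5),
                    sigma_individual = 0, sigma_cell = 0, sigma_resid = 0.7)
  tr <- simulate_tracks(ls1, sim_config(n_individuals = 25, days_per_individual = 200,
                                        missingness_rate = 0, seed = 9), tt)
  expect_gte(nrow(tr$days), 5000)
  slope <- coef(lm(sqrt_daily_distance ~ settlement_density, data = tr$days))[2]
  expect_lt(abs(slope + 0.5), 0.05)
})

test_that("grid-cell random effects are wired into the simulation", {
  ls1 <- generate_landscape(landscape_config(extent_km = c(10, 10), seed = 7))
  tt <- truth_table(beta = c("(Intercept)" = 2.9), sigma_individual = 0,
                    sigma_cell = 0.5, sigma_resid = 0.5)
  tr <- simulate_tracks(ls1, sim_config(n_individuals = 8, days_per_individual = 100,
                                        seed = 2), tt)
  d <- tr$days
  # positive intraclass correlation of day responses grouped by cell
  a <- anova(lm(sqrt_daily_distance ~ grid_cell_id, data = d))
  ms_b <- a$`Mean Sq`[1]; ms_w <- a$`Mean Sq`[2]
  n_per <- mean(table(d$grid_cell_id))
  icc <- (ms_b - ms_w) / (ms_b + (n_per - 1) * ms_w)
  expect_gt(icc, 0.1)
  expect_lt(a$`Pr(>F)`[1], 1e-6)
})

test_that("truth referencing unknown predictors is rejected", {
  ls1 <- generate_landscape(landscape_config(extent_km = c(2, 2), seed = 5))
  tt <- truth_table(beta = c("(Intercept)" = 2.9, prey_biomass = 0.5))
  expect_error(simulate_tracks(ls1, sim_config(n_individuals = 2,
                                               days_per_individual = 5, seed = 1), tt),
               "absent from the landscape")
})
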