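# Probability of Direction, pseudo-R2, posterior predictions with overrides,
# variance partitioning mechanics and marginal-effect grids.

test_that("probability of direction counts draw signs", {
  expect_equal(probability_of_direction(c(rep(1, 950), rep(-1, 50)))$pd, 0.95)
  expect_equal(probability_of_direction(rep(2.5, 200))$pd, 1)
  set.seed(2)
  sym <- rnorm(20000)
  expect_equal(probability_of_direction(sym)$pd, 0.5, tolerance = 0.02)
  expect_equal(probability_of_direction(rep(0, 500))$pd, 0.5)
  expect_error(probability_of_direction(rnorm(50)), "100 draws")
})

test_that("PD and credible intervals agree on significance", {
  fit <- small_gauss_fit()
  pd <- probability_of_direction(fit)
  expect_true(all(pd$pd >= 0.5 & pd$pd <= 1))
  expect_true(all(pd$pd[pd$significant] > 0.975))
  expect_true(all(pd$credible_direction == (pd$pd > 0.9)))
})

test_that("pseudo-R2 is a squared correlation", {
  set.seed(3)
  obs <- rnorm(100, 10, 3)
  expect_equal(pseudo_r2(obs, obs), 1)
  expect_equal(pseudo_r2(obs, 2 + 0.5 * obs), 1, tolerance = 1e-12)
  noise <- rnorm(10000); noise2 <- rnorm(10000)
  expect_lt(pseudo_r2(noise, noise2), 0.01)
  expect_error(pseudo_r2(obs, rep(1, 100)), "zero-variance")
  expect_error(pseudo_r2(obs, obs[1:50]), "equal-length")
})

test_that("neutralising every fixed term collapses to intercept plus REs", {
  fit <- small_gauss_fit()
  rec <- fit$records
  # the fit was built on already-standardised columns, so 0 is the mean
  p <- posterior_predict(fit, overrides = list(tri = 0, refuge_dim1 = 0),
                         scale = "link")
  # expected: median over draws of intercept + u + v per record
  iu <- match(rec$individual_id, fit$ind_levels)
  iv <- match(rec$grid_cell_id, fit$cell_levels)
  manual <- vapply(seq_len(nrow(rec)), function(i) {
    stats::median(fit$draws[, "(Intercept)"] +
                    fit$draws[, paste0("u[", iu[i], "]")] +
                    fit$draws[, paste0("v[", iv[i], "]")])
  }, 0)
  expect_equal(p, manual, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("raising a positive-slope predictor raises predictions", {
  fit <- small_gauss_fit()
  pd <- probability_of_direction(fit, "refuge_dim1")
  expect_gt(pd$pd, 0.99)  # strong simulated effect
  lo <- posterior_predict(fit, overrides = list(refuge_dim1 = -1), scale = "link")
  hi <- posterior_predict(fit, overrides = list(refuge_dim1 = 1), scale = "link")
  expect_true(all(hi > lo))
})

test_that("novel random-effect levels predict at the population level", {
  fit <- small_gauss_fit()
  p0 <- posterior_predict(fit, overrides = list(individual_id = "new",
                                                grid_cell_id = "new"),
                          scale = "link")
  manual <- vapply(seq_len(nrow(fit$records)), function(i)
    stats::median(fit$design$X[i, , drop = FALSE] %*%
                    t(fit$draws[, colnames(fit$design$X)])), 0)
  expect_equal(p0, manual, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(posterior_predict(fit, overrides = list(prey = 1)), "unknown term")
})

test_that("median predictions correlate with observations", {
  fit <- small_gauss_fit()
  p <- posterior_predict(fit)
  r2 <- pseudo_r2(fit$records$daily_distance, p)
  expect_gt(r2, 0.3)
})

test_that("variance partitioning is deterministic and accounts for terms", {
  fit <- small_gauss_fit()
  vp1 <- variance_partition(fit)
  vp2 <- variance_partition(fit)
  expect_identical(vp1$terms, vp2$terms)
  expect_identical(vp1$baseline_pseudo_r2, vp2$baseline_pseudo_r2)
  expect_setequal(vp1$terms$term,
                  c("tri", "refuge_dim1", "individual_id", "grid_cell_id"))
  expect_true(all(vp1$terms$drop >= 0))
  # floored percentages never negative
  expect_true(all(vp1$terms$pct_contribution >= 0))
  # both simulated slopes matter: their contributions are positive
  expect_gt(vp1$terms$drop[vp1$terms$term == "tri"], 0)
  expect_gt(vp1$terms$drop[vp1$terms$term == "refuge_dim1"], 0)
  # groups sum the term percentages
  expect_equal(sum(vp1$groups$pct_contribution),
               sum(vp1$terms$pct_contribution), tolerance = 1e-9)
})

test_that("marginal effect grids have coherent bands", {
  fit <- small_gauss_fit()
  me <- marginal_effects(fit, "refuge_dim1", n_grid = 15)
  expect_equal(nrow(me), 15L)
  expect_true(all(me$lo95 <= me$median & me$median <= me$hi95))
  # positive slope shows in the curve
  expect_gt(me$median[15], me$median[1])
  me2 <- marginal_effects(fit, "tri", moderator = "refuge_dim1", n_grid = 5)
  expect_equal(nrow(me2), 10L)
  expect_setequal(unique(me2$moderator_label), c("Q1", "Q3"))
  expect_error(marginal_effects(fit, "prey_biomass"), "unknown focal")
})
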