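# Period coding, stratified subsampling, design standardisation and the
# JAGS model fits at small scale.

test_that("reproductive periods follow the month rule", {
  expect_equal(assign_period(as.Date("2011-03-15")), "mating")
  expect_equal(assign_period(as.Date("2011-07-01")), "breeding")
  expect_equal(assign_period(as.Date("2011-01-02")), "nonreproductive")
  expect_equal(assign_period(as.Date(c("2011-02-01", "2011-04-30",
                                       "2011-05-01", "2011-10-31",
                                       "2011-11-01", "2011-12-31"))),
               c("mating", "mating", "breeding", "breeding",
                 "nonreproductive", "nonreproductive"))
})

test_that("stratified subsampling keeps two thirds per individual-month", {
  rec3 <- data.frame(individual_id = "a",
                     track_date = as.Date("2010-06-01") + 0:2)
  expect_equal(nrow(subsample_two_thirds(rec3, seed = 1)), 2L)

  # determinism
  big <- data.frame(individual_id = rep(sprintf("w%02d", 1:20), each = 200),
                    track_date = as.Date("2010-01-01") + 0:199)
  s1 <- subsample_two_thirds(big, seed = 5)
  s2 <- subsample_two_thirds(big, seed = 5)
  expect_identical(s1, s2)
  expect_false(identical(s1, subsample_two_thirds(big, seed = 6)))

  # overall kept fraction within 1% of 2/3 on 4,000 tracks
  expect_lt(abs(nrow(s1) / nrow(big) - 2 / 3), 0.01)

  # strata are respected: per individual-month fraction near 2/3
  mo <- function(d) format(as.Date(d$track_date), "%Y-%m")
  tab_all <- table(paste(big$individual_id, mo(big)))
  tab_kept <- table(paste(s1$individual_id, mo(s1)))
  frac <- as.numeric(tab_kept[names(tab_all)]) / as.numeric(tab_all)
  expect_true(all(abs(frac - 2 / 3) < 0.06))
})

test_that("design matrices standardise continuous predictors exactly", {
  set.seed(8)
  rec <- data.frame(tri = rnorm(100, 5, 3), refuge_dim1 = runif(100, -2, 9),
                    sex = sample(c("F", "M"), 100, TRUE),
                    period = sample(c("breeding", "mating"), 100, TRUE))
  des <- build_design(rec, terms = c("sex", "period", "tri", "refuge_dim1"),
                      interactions = c("tri:refuge_dim1", "sex:period"))
  for (cn in c("tri", "refuge_dim1")) {
    expect_lt(abs(mean(des$X[, cn])), 1e-8)
    expect_lt(abs(sd(des$X[, cn]) - 1), 1e-8)
  }
  # interaction columns are products of the standardised parents
  expect_equal(des$X[, "tri:refuge_dim1"],
               des$X[, "tri"] * des$X[, "refuge_dim1"], tolerance = 1e-12)
  expect_equal(des$X[, "sexM:periodmating"],
               des$X[, "sexM"] * des$X[, "periodmating"], tolerance = 1e-12)
  # term bookkeeping
  expect_equal(unname(des$term_of["sexM:periodmating"]), "sex:period")
  expect_error(build_design(rec, terms = "tri", interactions = "tri:slope"),
               "interaction")
})

test_that("a small Gaussian hierarchical fit recovers structure", {
  fit <- small_gauss_fit()
  rec <- sim_gauss_records()
  truth <- attr(rec, "beta")
  s <- summary(fit)
  expect_lt(max(fit$rhat$rhat, na.rm = TRUE), 1.05)
  # strong slopes recovered with correct sign and rough magnitude
  expect_lt(abs(s$median[s$parameter == "tri"] - truth[["tri"]]), 0.1)
  expect_lt(abs(s$median[s$parameter == "refuge_dim1"] - truth[["refuge_dim1"]]), 0.1)
  # residual mean ~ 0 on the fitting scale
  expect_lt(abs(mean(residuals(fit))), 0.05)
  # back-transformed fitted values are nonnegative
  expect_true(all(posterior_predict(fit) >= 0))
})

test_that("prior-only sampling reproduces the prior scales", {
  fit <- fit_movement_model(data.frame(), prior_only = TRUE, chains = 2,
                            iter = 3000, warmup = 500, seed = 3)
  b <- fit$draws
  expect_equal(sd(b[, "slope"]), 1, tolerance = 0.1)
  expect_equal(sd(b[, "(Intercept)"]), 10, tolerance = 1)
  expect_lt(abs(mean(b[, "slope"])), 0.1)
})

test_that("an all-zero straightness sample drives the zero-inflation to one", {
  rec <- simulate_zib_records(n = 150, pi = 1, seed = 4)
  expect_true(all(rec$straightness == 0))
  fit <- fit_movement_model(rec, "straightness", terms = "tri",
                            interactions = character(0), chains = 2,
                            iter = 800, warmup = 300, seed = 5)
  expect_gt(mean(fit$draws[, "pi"]), 0.95)
})

test_that("straightness boundary values are compressed, NAs dropped", {
  rec <- simulate_zib_records(n = 120, pi = 0.05, seed = 9)
  rec$straightness[1:3] <- 1     # exact 1s excluded by the Beta support
  rec$straightness[4:5] <- NA    # undefined (zero daily distance)
  fit <- fit_movement_model(rec, "straightness", terms = "tri",
                            interactions = character(0), chains = 2,
                            iter = 600, warmup = 250, seed = 5)
  expect_equal(length(fit$y), 118)      # NAs excluded
  expect_true(all(fit$y < 1))           # boundary compressed
  expect_true(all(fit$y[4:118] <= 1))
})

test_that("invalid responses and unseen levels fail loudly", {
  rec <- sim_gauss_records(n = 50)
  rec$daily_distance[2] <- -1
  expect_error(fit_movement_model(rec, "daily_distance", terms = "tri",
                                  interactions = character(0)),
               "nonnegative")
  fit <- small_gauss_fit()
  nd <- sim_gauss_records(n = 10, seed = 3)
  nd$sex <- "X"  # not a valid level
  expect_error(build_design(nd, terms = c("sex"), interactions = character(0)),
               "unseen level")
})
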