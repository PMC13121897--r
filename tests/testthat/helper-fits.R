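# Small simulated datasets and cached model fits shared across test files.
# Direct draws from the model likelihoods (not the movement simulator), so
# model-stack tests are independent of the track generator.

sim_gauss_records <- function(n = 500, beta = c("(Intercept)" = 2.8,
                                                tri = -0.3, refuge_dim1 = 0.4),
                              sigma_u = 0.2, sigma_v = 0.3, sigma = 0.5,
                              n_ind = 8, n_cell = 20, seed = 2) {
  set.seed(seed)
  rec <- data.frame(
    individual_id = sample(sprintf("ind%02d", 1:n_ind), n, TRUE),
    grid_cell_id = sample(sprintf("%d_%d", rep(1:5, 4), rep(1:4, each = 5))[1:n_cell],
                          n, TRUE),
    tri = rnorm(n), refuge_dim1 = rnorm(n))
  # one record per individual-day, as the track pipeline guarantees
  rec$track_date <- as.Date("2010-01-01") +
    stats::ave(seq_len(n), rec$individual_id, FUN = seq_along) * 2L
  u <- rnorm(n_ind, 0, sigma_u)
  v <- rnorm(n_cell, 0, sigma_v)
  ui <- u[as.integer(factor(rec$individual_id, sort(unique(rec$individual_id))))]
  vi <- v[as.integer(factor(rec$grid_cell_id, sort(unique(rec$grid_cell_id))))]
  eta <- beta[["(Intercept)"]] + beta[["tri"]] * rec$tri +
    beta[["refuge_dim1"]] * rec$refuge_dim1 + ui + vi
  rec$sqrt_true <- eta
  rec$daily_distance <- pmax(0, rnorm(n, eta, sigma))^2
  attr(rec, "beta") <- beta
  rec
}

.fit_cache <- new.env(parent = emptyenv())

# One modest Gaussian fit reused by prediction/inference/diagnostic tests.
small_gauss_fit <- function() {
  if (is.null(.fit_cache$gauss)) {
    rec <- sim_gauss_records()
    .fit_cache$gauss_records <- rec
    .fit_cache$gauss <- fit_movement_model(
      rec, "daily_distance", terms = c("tri", "refuge_dim1"),
      interactions = character(0), chains = 2, iter = 1200, warmup = 400,
      standardize = FALSE, seed = 7)
  }
  .fit_cache$gauss
}
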