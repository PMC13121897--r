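#' Reproductive period of a track date
#'
#' February-April is the mating season, May-October the breeding season and
#' November-January the nonreproductive period.
#'
#' @param track_date Date vector (or anything `as.Date()` accepts).
#' @return character vector over `c("mating", "breeding", "nonreproductive")`.
#' @export
assign_period <- function(track_date) {
  m <- as.integer(format(as.Date(track_date), "%m"))
  out <- rep("nonreproductive", length(m))
  out[m %in% 2:4] <- "mating"
  out[m %in% 5:10] <- "breeding"
  out
}

#' Stratified two-thirds subsample of daily tracks
#'
#' Temporal autocorrelation between consecutive daily tracks is broken by
#' random subsampling rather than autoregressive error terms. Within every
#' individual-by-calendar-month stratum, `floor(2n/3)` tracks are kept plus
#' one more with probability equal to the fractional remainder, so the
#' expected kept fraction is exactly 2/3 while strata of 3 keep exactly 2.
#' Deterministic under `seed`.
#'
#' @param records data.frame with `individual_id` and `track_date`.
#' @param seed integer seed.
#' @return the subsampled records (original row order preserved).
#' @export
subsample_two_thirds <- function(records, seed = 1L) {
  if (!all(c("individual_id", "track_date") %in% names(records)))
    stop_predmove("records need individual_id and track_date")
  month <- format(as.Date(records$track_date), "%Y-%m")
  strat <- paste(records$individual_id, month)
  with_seed(seed, {
    keep <- logical(nrow(records))
    for (s in unique(strat)) {
      i <- which(strat == s)
      n <- length(i)
      m <- floor(2 * n / 3)
      if (stats::runif(1) < (2 * n / 3 - m)) m <- m + 1L
      if (m > 0) keep[sample(i, m)] <- TRUE
    }
    records[keep, , drop = FALSE]
  })
}

# ---- JAGS model code -------------------------------------------------------

jags_code_gaussian <- "
model {
  for (i in 1:N) {
    mu[i] <- inprod(X[i,], b) + u[ind[i]] + v[cell[i]]
    y[i] ~ dnorm(mu[i], tau)
  }
  b[1] ~ dnorm(0, 0.01)
  for (j in 2:P) { b[j] ~ dnorm(0, 1) }
  for (k in 1:J) { u[k] ~ dnorm(0, tau_u) }
  for (k in 1:K) { v[k] ~ dnorm(0, tau_v) }
  sigma ~ dt(0, 0.16, 3) T(0,)
  sigma_u ~ dt(0, 0.16, 3) T(0,)
  sigma_v ~ dt(0, 0.16, 3) T(0,)
  tau <- 1 / (sigma * sigma)
  tau_u <- 1 / (sigma_u * sigma_u)
  tau_v <- 1 / (sigma_v * sigma_v)
}"

jags_code_zib <- "
model {
  for (i in 1:N) { z[i] ~ dbern(pi) }
  for (m in 1:M) {
    logit(mu[m]) <- inprod(Xp[m,], b) + u[indp[m]] + v[cellp[m]]
    ypos[m] ~ dbeta(mu[m] * phi, (1 - mu[m]) * phi)
  }
  pi ~ dbeta(1, 1)
  b[1] ~ dnorm(0, 0.01)
  for (j in 2:P) { b[j] ~ dnorm(0, 1) }
  for (k in 1:J) { u[k] ~ dnorm(0, tau_u) }
  for (k in 1:K) { v[k] ~ dnorm(0, tau_v) }
  phi ~ dt(0, 0.01, 3) T(0,)
  sigma_u ~ dt(0, 0.16, 3) T(0,)
  sigma_v ~ dt(0, 0.16, 3) T(0,)
  tau_u <- 1 / (sigma_u * sigma_u)
  tau_v <- 1 / (sigma_v * sigma_v)
}"

# degenerate zero-inflated Beta with no positive observations: only the
# zero-mass part is informed by data
jags_code_zib_empty <- "
model {
  for (i in 1:N) { z[i] ~ dbern(pi) }
  pi ~ dbeta(1, 1)
  b[1] ~ dnorm(0, 0.01)
  for (j in 2:P) { b[j] ~ dnorm(0, 1) }
  phi ~ dt(0, 0.01, 3) T(0,)
  sigma_u ~ dt(0, 0.16, 3) T(0,)
  sigma_v ~ dt(0, 0.16, 3) T(0,)
}"

jags_code_prior_only <- "
model {
  b[1] ~ dnorm(0, 0.01)
  for (j in 2:P) { b[j] ~ dnorm(0, 1) }
  sigma ~ dt(0, 0.16, 3) T(0,)
  sigma_u ~ dt(0, 0.16, 3) T(0,)
  sigma_v ~ dt(0, 0.16, 3) T(0,)
}"

#' Fit a Bayesian hierarchical movement model
#'
#' Fits one of the three daily movement responses against the full a-priori
#' fixed-effect and interaction structure with random intercepts for the
#' individual and the 1x1 km grid cell, via MCMC in JAGS.
#'
#' * `daily_distance` and `net_displacement`: Gaussian likelihood on the
#'   square-root scale.
#' * `straightness`: zero-inflated Beta. Exact zeros arise with probability
#'   `pi`; positive values follow `Beta(mu*phi, (1-mu)*phi)` with a logit
#'   link on `mu`. Straightness values of exactly 1 (excluded by the Beta
#'   support) are compressed by `y' = (y(n-1) + 0.5)/n` applied to boundary
#'   values only; undefined straightness rows (zero daily distance) are
#'   dropped from this model.
#'
#' Priors: Normal(0, 10) on the intercept, Normal(0, 1) on slopes (all
#' continuous predictors standardised), half-Student-t(3, 0, 2.5) on SDs and
#' half-Student-t(3, 0, 10) on the Beta precision. Defaults run 4 chains of
#' 4,000 iterations with 2,000 warmup (adaptation + burn-in); tests and
#' quick runs can reduce this via the arguments.
#'
#' @param records data.frame with the response column, all predictor columns
#'   ([default_terms()]), `individual_id` and `grid_cell_id`.
#' @param response `"daily_distance"`, `"net_displacement"` or
#'   `"straightness"`. The matching column may also be named with the
#'   `_km` suffix used by [track_metrics()].
#' @param terms,interactions fixed-effect structure (see [build_design()]).
#' @param chains,iter,warmup MCMC configuration; `iter` counts total
#'   iterations per chain of which `warmup` are discarded.
#' @param standardize standardise continuous predictors (set FALSE only when
#'   columns are already on a standardised scale, e.g. simulator output).
#' @param prior_only sample the prior instead of the posterior (no data).
#' @param seed integer seed for the JAGS RNGs.
#' @param quiet suppress JAGS progress output.
#' @return object of class `movement_fit`: draws matrix (all chains
#'   stacked, with `chain` attribute), design metadata, per-parameter R-hat,
#'   the training records, and fitted response info.
#' @export
fit_movement_model <- function(records,
                               response = c("daily_distance",
                                            "net_displacement",
                                            "straightness"),
                               terms = default_terms(),
                               interactions = default_interactions(),
                               chains = 4, iter = 4000, warmup = 2000,
                               standardize = TRUE, prior_only = FALSE,
                               seed = 1L, quiet = TRUE) {
  response <- match.arg(response)
  family <- if (response == "straightness") "zib" else "gaussian_sqrt"

  ycol <- if (response %in% names(records)) response else paste0(response, "_km")
  if (!prior_only && !ycol %in% names(records))
    stop_predmove("response column '", response, "' not found")

  if (!prior_only) {
    y_raw <- records[[ycol]]
    if (family == "zib") {
      ok <- !is.na(y_raw)
      records <- records[ok, , drop = FALSE]
      y_raw <- y_raw[ok]
      if (any(y_raw < 0 | y_raw > 1))
        stop_predmove("straightness must lie in [0, 1]")
      n <- length(y_raw)
      y <- ifelse(y_raw >= 1, (y_raw * (n - 1) + 0.5) / n, y_raw)
    } else {
      if (any(!is.finite(y_raw)) || any(y_raw < 0))
        stop_predmove("response must be finite and nonnegative")
      y <- sqrt(y_raw)
    }
  }

  des <- if (prior_only) {
    list(X = matrix(0, 0, 2, dimnames = list(NULL, c("(Intercept)", "slope"))),
         center = numeric(), scale = numeric(),
         term_of = c(`(Intercept)` = "(Intercept)", slope = "slope"),
         terms = terms, interactions = interactions)
  } else {
    build_design(records, terms, interactions, standardize = standardize)
  }

  if (prior_only) {
    data <- list(P = 2L)
    code <- jags_code_prior_only
    monitors <- c("b", "sigma", "sigma_u", "sigma_v")
    ind_levels <- cell_levels <- character()
  } else {
    ind_levels <- sort(unique(as.character(records$individual_id)))
    cell_levels <- sort(unique(as.character(records$grid_cell_id)))
    ind <- match(as.character(records$individual_id), ind_levels)
    cell <- match(as.character(records$grid_cell_id), cell_levels)
    if (family == "gaussian_sqrt") {
      data <- list(N = length(y), P = ncol(des$X), J = length(ind_levels),
                   K = length(cell_levels), X = des$X, y = y,
                   ind = ind, cell = cell)
      code <- jags_code_gaussian
      monitors <- c("b", "sigma", "sigma_u", "sigma_v", "u", "v")
    } else if (any(y > 0)) {
      pos <- which(y > 0)
      data <- list(N = length(y), M = length(pos), P = ncol(des$X),
                   J = length(ind_levels), K = length(cell_levels),
                   z = as.integer(y == 0), Xp = des$X[pos, , drop = FALSE],
                   ypos = y[pos], indp = ind[pos], cellp = cell[pos])
      code <- jags_code_zib
      monitors <- c("b", "pi", "phi", "sigma_u", "sigma_v", "u", "v")
    } else {
      data <- list(N = length(y), P = ncol(des$X), z = as.integer(y == 0))
      code <- jags_code_zib_empty
      monitors <- c("b", "pi", "phi", "sigma_u", "sigma_v")
    }
  }

  inits <- lapply(seq_len(chains), function(ch) list(
    .RNG.name = "base::Mersenne-Twister",
    .RNG.seed = as.integer(seed) * 1000L + ch))
  loaded <- try(rjags::load.module("glm", quiet = TRUE), silent = TRUE)
  jm <- rjags::jags.model(textConnection(code), data = data, inits = inits,
                          n.chains = chains, n.adapt = max(100, warmup),
                          quiet = quiet)
  samp <- rjags::coda.samples(jm, monitors, n.iter = max(iter - warmup, 100),
                              progress.bar = if (quiet) "none" else "text")

  rhat <- if (chains >= 2) {
    gd <- try(coda::gelman.diag(samp, autoburnin = FALSE,
                                multivariate = FALSE)$psrf, silent = TRUE)
    if (inherits(gd, "try-error")) NULL else
      data.frame(parameter = rownames(gd), rhat = gd[, 1], row.names = NULL)
  } else NULL

  dm <- do.call(rbind, lapply(samp, as.matrix))
  chain_id <- rep(seq_len(chains), each = nrow(samp[[1]]))
  # rename b[i] to design column names
  bcols <- paste0("b[", seq_len(ncol(des$X)), "]")
  colnames(dm)[match(bcols, colnames(dm))] <- colnames(des$X)

  fit <- structure(list(
    draws = dm, chain = chain_id, family = family, response = response,
    design = des, records = if (prior_only) NULL else records,
    y = if (prior_only) NULL else y,
    ind_levels = ind_levels, cell_levels = cell_levels,
    rhat = rhat, chains = chains, iter = iter, warmup = warmup,
    terms = terms, interactions = interactions,
    adapted = !isTRUE(inherits(loaded, "try-error"))
  ), class = "movement_fit")
  fit
}

#' @export
print.movement_fit <- function(x, ...) {
  cat("Bayesian movement model:", x$response,
      sprintf("(%s), %d chains x %d kept draws\n",
              if (x$family == "zib") "zero-inflated Beta"
              else "Gaussian on sqrt scale",
              x$chains, nrow(x$draws) / x$chains))
  if (!is.null(x$rhat))
    cat("  max R-hat:", sprintf("%.3f", max(x$rhat$rhat, na.rm = TRUE)), "\n")
  if (!is.null(x$records)) cat("  n =", nrow(x$records), "tracks\n")
  invisible(x)
}

#' Posterior summary of the fixed effects
#'
#' @param object a `movement_fit`.
#' @param prob mass of the equal-tailed credible interval.
#' @param ... unused.
#' @return data.frame: parameter, term, median, ci_low, ci_high, rhat.
#' @export
summary.movement_fit <- function(object, prob = 0.95, ...) {
  cn <- colnames(object$design$X)
  a <- (1 - prob) / 2
  d <- object$draws[, cn, drop = FALSE]
  out <- data.frame(
    parameter = cn,
    term = unname(object$design$term_of[cn]),
    median = apply(d, 2, stats::median),
    ci_low = apply(d, 2, quantile_lin, a),
    ci_high = apply(d, 2, quantile_lin, 1 - a),
    row.names = NULL)
  if (!is.null(object$rhat)) {
    bmap <- paste0("b[", seq_along(cn), "]")
    out$rhat <- object$rhat$rhat[match(bmap, object$rhat$parameter)]
  }
  out
}

#' Serialise a fit to plain-text files
#'
#' Writes the stacked draws as CSV and a JSON summary (coefficient medians,
#' credible intervals, R-hat, MCMC configuration).
#'
#' @param fit a `movement_fit`.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  draws_path <- file.path(dir, paste0(fit$response, "_draws.csv"))
  sum_path <- file.path(dir, paste0(fit$response, "_summary.json"))
  utils::write.csv(data.frame(chain = fit$chain, fit$draws,
                              check.names = FALSE),
                   draws_path, row.names = FALSE)
  jsonlite::write_json(list(
    response = fit$response, family = fit$family,
    chains = fit$chains, iter = fit$iter, warmup = fit$warmup,
    coefficients = summary(fit),
    max_rhat = if (!is.null(fit$rhat)) max(fit$rhat$rhat, na.rm = TRUE) else NA
  ), sum_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(draws = draws_path, summary = sum_path))
}
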