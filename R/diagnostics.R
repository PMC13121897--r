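#' Within-individual residual autocorrelation over daily lags
#'
#' For each lag k (days), pairs the residuals of every individual that are
#' exactly k days apart; gaps from subsampled-out days simply produce no
#' pair (lag chains are broken, never bridged). The estimator is
#' `r_k = mean over pairs of (e_i - m)(e_j - m) / (mean over all of (e - m)^2)`
#' with `m` the pooled residual mean, so `r_0 = 1` by construction.
#' Individuals contributing fewer than 3 residuals are skipped.
#'
#' @param residuals numeric residual vector.
#' @param individual_id,date vectors aligned with `residuals`.
#' @param max_lag largest lag in days.
#' @return data.frame: lag, acf, n_pairs, z (acf * sqrt(n_pairs)), p
#'   (two-sided normal). Lag 0 has p = NA.
#' @export
residual_acf <- function(residuals, individual_id, date, max_lag = 10) {
  date <- as.integer(as.Date(date))
  if (anyDuplicated(paste(individual_id, date)))
    stop_predmove("duplicate individual-date pairs; aggregate to one residual per day first")
  keep_ids <- names(which(table(individual_id) >= 3))
  keep <- individual_id %in% keep_ids
  e <- residuals[keep]; id <- individual_id[keep]; dt <- date[keep]
  if (length(e) < 3) stop_predmove("need at least 3 residuals after skipping")
  m <- mean(e)
  denom <- mean((e - m)^2)
  rows <- lapply(0:max_lag, function(k) {
    num <- 0; npair <- 0L
    for (g in split(seq_along(e), id)) {
      dg <- dt[g]; eg <- e[g] - m
      match_j <- match(dg + k, dg)
      ok <- !is.na(match_j)
      if (any(ok)) {
        num <- num + sum(eg[ok] * eg[match_j[ok]])
        npair <- npair + sum(ok)
      }
    }
    acf_k <- if (npair > 0) (num / npair) / denom else NA_real_
    z <- if (k > 0 && npair > 0) acf_k * sqrt(npair) else NA_real_
    data.frame(lag = k, acf = acf_k, n_pairs = npair, z = z,
               p = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Moran's I spatial autocorrelation with a normality-based test
#'
#' `I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with expectation `-1/(n-1)` under no autocorrelation. Weights are either
#' inverse distance with a cutoff (default: 5 km, the scale separating
#' adjacent from distant daily tracks) or k-nearest-neighbour row indicators.
#' The z score and two-sided p use the variance under the normality
#' assumption.
#'
#' @param x numeric values (e.g. model residuals), length >= 10.
#' @param coords matrix/data.frame of planar km coordinates (2 columns).
#' @param weights `"idw"` or `"knn"`.
#' @param cutoff_km inverse-distance cutoff (idw).
#' @param k neighbour count (knn).
#' @param W optional explicit weight matrix (overrides `weights`); zero
#'   diagonal required.
#' @return list: statistic, expectation, variance, z, p.
#' @export
morans_i <- function(x, coords, weights = c("idw", "knn"), cutoff_km = 5,
                     k = 8, W = NULL) {
  n <- length(x)
  if (n < 10) stop_predmove("need at least 10 points")
  xc <- x - mean(x)
  if (sum(xc^2) == 0) stop_predmove("zero residual variance")
  coords <- as.matrix(coords)
  if (is.null(W)) {
    weights <- match.arg(weights)
    d <- as.matrix(stats::dist(coords))
    if (weights == "idw") {
      W <- ifelse(d > 0 & d <= cutoff_km, 1 / d, 0)
    } else {
      W <- matrix(0, n, n)
      for (i in seq_len(n)) {
        nb <- order(d[i, ])[2:(k + 1)]
        W[i, nb] <- 1
      }
    }
  }
  diag(W) <- 0
  S0 <- sum(W)
  if (S0 == 0) stop_predmove("empty spatial weights (no pairs within cutoff)")
  I <- (n / S0) * drop(t(xc) %*% W %*% xc) / sum(xc^2)
  EI <- -1 / (n - 1)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  VI <- (n^2 * S1 - n * S2 + 3 * S0^2) / ((n^2 - 1) * S0^2) - EI^2
  z <- (I - EI) / sqrt(VI)
  list(statistic = I, expectation = EI, variance = VI, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Posterior predictive checks
#'
#' Simulates `n_reps` replicate response vectors from randomly chosen
#' posterior draws (full parameter vectors, including random effects) and
#' compares observed summary statistics against their replicate
#' distributions. Gaussian models check mean, SD, min and max on the fitting
#' (sqrt) scale; the zero-inflated Beta model additionally checks the
#' zero fraction. Tail probabilities are `P(T_rep >= T_obs)`; values near 0
#' or 1 flag misfit.
#'
#' @param fit a `movement_fit`.
#' @param n_reps number of replicate datasets.
#' @param seed seed for draw selection and simulation.
#' @return data.frame: statistic, observed, rep_mean, rep_lo95, rep_hi95,
#'   tail_prob.
#' @export
posterior_predictive_check <- function(fit, n_reps = 200, seed = 1L) {
  stopifnot(inherits(fit, "movement_fit"))
  eta <- posterior_predict(fit, scale = "link", return_draws = TRUE)
  with_seed(seed, {
    take <- sample(nrow(eta), n_reps, replace = n_reps > nrow(eta))
    y <- fit$y
    stats_of <- function(v) {
      s <- c(mean = mean(v), sd = stats::sd(v))
      if (fit$family == "zib") s <- c(s, zero_frac = mean(v == 0))
      s
    }
    reps <- vapply(take, function(r) {
      if (fit$family == "gaussian_sqrt") {
        yr <- stats::rnorm(ncol(eta), eta[r, ], fit$draws[r, "sigma"])
      } else {
        mu <- stats::plogis(eta[r, ])
        phi <- fit$draws[r, "phi"]
        yr <- stats::rbeta(ncol(eta), mu * phi, (1 - mu) * phi)
        yr[stats::runif(ncol(eta)) < fit$draws[r, "pi"]] <- 0
      }
      stats_of(yr)
    }, stats_of(y))
    obs <- stats_of(y)
    out <- data.frame(
      statistic = names(obs), observed = unname(obs),
      rep_mean = rowMeans(reps),
      rep_lo95 = apply(reps, 1, quantile_lin, 0.025),
      rep_hi95 = apply(reps, 1, quantile_lin, 0.975),
      tail_prob = vapply(seq_along(obs), function(i)
        mean(reps[i, ] >= obs[i]), 0))
    rownames(out) <- NULL
    out
  })
}

#' Full diagnostics report for a fitted movement model
#'
#' Bundles the R-hat maximum, within-individual residual ACF, Moran's I of
#' residuals at track mid-coordinates, and posterior predictive checks.
#'
#' Moran's I is evaluated on residuals averaged per 1x1 km grid cell at the
#' cell centres (analogous to aggregating DHARMa residuals per location):
#' repeated tracks share a cell, and per-record testing at coincident
#' coordinates would mostly measure the within-cell shrinkage of the cell
#' random effect rather than residual spatial structure.
#'
#' @param fit a `movement_fit`.
#' @param max_lag,n_reps,seed passed through.
#' @return object of class `diagnostics_report` (a list); see fields.
#' @export
diagnose_fit <- function(fit, max_lag = 10, n_reps = 200, seed = 1L) {
  rec <- fit$records
  res <- stats::residuals(fit)
  cell_mean <- tapply(res, rec$grid_cell_id, mean)
  parts <- do.call(rbind, strsplit(names(cell_mean), "_"))
  coords <- cbind(as.numeric(parts[, 1]) + 0.5, as.numeric(parts[, 2]) + 0.5)
  acf_tab <- residual_acf(res, rec$individual_id, rec$track_date, max_lag)
  mi <- morans_i(as.numeric(cell_mean), coords)
  ppc <- posterior_predictive_check(fit, n_reps = n_reps, seed = seed)
  structure(list(
    rhat_max = if (!is.null(fit$rhat)) max(fit$rhat$rhat, na.rm = TRUE) else NA,
    acf = acf_tab, morans_i = mi, ppc = ppc), class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("Model diagnostics\n")
  cat(sprintf("  max R-hat: %.3f\n", x$rhat_max))
  a1 <- x$acf[x$acf$lag == 1, ]
  cat(sprintf("  residual ACF lag 1: %.3f (p = %.3f)\n", a1$acf, a1$p))
  cat(sprintf("  Moran's I: %.4f (exp %.4f, p = %.3f)\n",
              x$morans_i$statistic, x$morans_i$expectation, x$morans_i$p))
  bad <- x$ppc$tail_prob < 0.05 | x$ppc$tail_prob > 0.95
  cat("  PPC statistics outside (0.05, 0.95):", sum(bad), "of", nrow(x$ppc), "\n")
  invisible(x)
}
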