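#' Probability of Direction of posterior draws
#'
#' The PD is the posterior probability that a parameter is strictly positive
#' or strictly negative, whichever is larger; it ranges from 0.5 (no
#' directional evidence) to 1. A PD above 0.9 is flagged as a credible
#' direction; significance additionally requires the equal-tailed 95%
#' credible interval to exclude zero.
#'
#' @param fit a `movement_fit`, or a numeric vector of draws for one
#'   parameter.
#' @param parameters for a fit, which design columns to summarise (default:
#'   all fixed-effect columns).
#' @return data.frame: parameter, pd, ci_low, ci_high, significant,
#'   credible_direction.
#' @export
probability_of_direction <- function(fit, parameters = NULL) {
  draws_of <- function(d) {
    if (length(d) < 100) stop_predmove("need at least 100 draws")
    pd <- max(mean(d > 0), mean(d < 0))
    if (all(d == 0)) pd <- 0.5
    ci <- quantile_lin(d, c(0.025, 0.975))
    data.frame(pd = pd, ci_low = ci[1], ci_high = ci[2],
               significant = ci[1] > 0 | ci[2] < 0,
               credible_direction = pd > 0.9)
  }
  if (is.numeric(fit)) {
    out <- cbind(data.frame(parameter = "draws"), draws_of(fit))
    return(out)
  }
  stopifnot(inherits(fit, "movement_fit"))
  parameters <- parameters %||% colnames(fit$design$X)
  out <- do.call(rbind, lapply(parameters, function(p)
    cbind(data.frame(parameter = p), draws_of(fit$draws[, p]))))
  rownames(out) <- NULL
  out
}

#' Predictive pseudo-R-squared
#'
#' The squared Pearson correlation between observed responses and the median
#' posterior predictions.
#'
#' @param observed,predicted numeric vectors of equal length (>= 3).
#' @return fraction in \[0, 1\].
#' @export
pseudo_r2 <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 3)
    stop_predmove("need equal-length vectors with at least 3 points")
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0)
    stop_predmove("zero-variance input to pseudo_r2")
  stats::cor(observed, predicted)^2
}

#' Default grouping of predictors for variance partitioning
#'
#' Mirrors the predictor factor classification: intrinsic traits,
#' anthropogenic disturbance, trophic resources, landscape attributes,
#' refuge cover, and random effects. Interactions belong to the group of
#' their first-named parent (road-by-refuge buffering counts as
#' anthropogenic); this map is configuration, not hard-coded behaviour.
#'
#' @return named character vector: term -> group.
#' @export
default_group_map <- function() {
  c(age = "intrinsic", sex = "intrinsic", status = "intrinsic",
    period = "intrinsic", "sex:period" = "intrinsic",
    "status:period" = "intrinsic",
    pop_density = "anthropogenic", settlement_density = "anthropogenic",
    primary_road = "anthropogenic", secondary_road = "anthropogenic",
    "pop_density:settlement_density" = "anthropogenic",
    "primary_road:refuge_dim1" = "anthropogenic",
    "primary_road:refuge_dim2" = "anthropogenic",
    "secondary_road:refuge_dim1" = "anthropogenic",
    "secondary_road:refuge_dim2" = "anthropogenic",
    diet = "trophic", tri = "landscape",
    refuge_dim1 = "refuge", refuge_dim2 = "refuge",
    "refuge_dim1:refuge_dim2" = "refuge",
    individual_id = "random", grid_cell_id = "random")
}

#' Variance partitioning by predictive pseudo-R-squared drops
#'
#' The baseline pseudo-R2 comes from unmodified median posterior
#' predictions. Each term is then neutralised in turn and predictions are
#' recomputed: a continuous term is held at its training mean (interactions
#' involving it are rebuilt from the neutralised value); a categorical term
#' is fixed to each of its levels in turn and the resulting drops averaged
#' (unweighted; frequency-weighted averages are also reported); an
#' interaction term has its design columns fixed at their training means
#' while its parents keep their data values; a random effect is replaced by
#' a single level absent from the training data. The drop in pseudo-R2
#' measures the term's contribution, expressed as a percentage of the
#' baseline. Negative drops (possible by chance) are kept in `drop_raw` and
#' floored at zero for percentages.
#'
#' @param fit a `movement_fit`.
#' @param records records to evaluate on (default: training records).
#' @param group_map named term -> group vector ([default_group_map()]).
#' @param observed_scale `"natural"` (default) or `"link"`: the scale on
#'   which observed responses and predictions are correlated.
#' @return object of class `variance_partition`: list with
#'   `baseline_pseudo_r2`, `terms` (term, drop_raw, drop, pct_contribution,
#'   pct_weighted for categoricals, group) and `groups` (summed percentages).
#' @export
variance_partition <- function(fit, records = NULL,
                               group_map = default_group_map(),
                               observed_scale = c("natural", "link")) {
  stopifnot(inherits(fit, "movement_fit"))
  observed_scale <- match.arg(observed_scale)
  rec <- records %||% fit$records
  obs <- if (fit$family == "gaussian_sqrt") {
    if (observed_scale == "natural") fit$y^2 else fit$y
  } else fit$y
  pscale <- if (fit$family == "zib") "natural" else observed_scale
  base_pred <- posterior_predict(fit, rec, scale = pscale)
  baseline <- pseudo_r2(obs, base_pred)

  all_terms <- c(fit$terms, fit$interactions, "individual_id", "grid_cell_id")
  rows <- lapply(all_terms, function(tm) {
    wmean <- NA_real_
    if (tm %in% names(predmove_levels)) {
      lv <- predmove_levels[[tm]]
      drops <- vapply(lv, function(l) {
        p <- posterior_predict(fit, rec, overrides = stats::setNames(list(l), tm),
                               scale = pscale)
        baseline - pseudo_r2(obs, p)
      }, 0)
      drop <- mean(drops)
      freq <- table(factor(rec[[tm]], levels = lv)) / nrow(rec)
      wmean <- sum(drops * as.numeric(freq))
    } else if (tm %in% c("individual_id", "grid_cell_id")) {
      p <- posterior_predict(fit, rec, overrides = stats::setNames(list("new"), tm),
                             scale = pscale)
      drop <- baseline - pseudo_r2(obs, p)
    } else if (tm %in% fit$interactions) {
      p <- posterior_predict(fit, rec, overrides = stats::setNames(list(TRUE), tm),
                             scale = pscale)
      drop <- baseline - pseudo_r2(obs, p)
    } else {
      p <- posterior_predict(fit, rec,
                             overrides = stats::setNames(
                               list(fit$design$center[[tm]]), tm),
                             scale = pscale)
      drop <- baseline - pseudo_r2(obs, p)
    }
    data.frame(term = tm, drop_raw = drop, drop = max(0, drop),
               weighted_drop = wmean)
  })
  tab <- do.call(rbind, rows)
  tab$pct_contribution <- 100 * tab$drop / baseline
  tab$pct_weighted <- ifelse(is.na(tab$weighted_drop), NA,
                             100 * pmax(0, tab$weighted_drop) / baseline)
  tab$group <- unname(group_map[tab$term])
  tab$group[is.na(tab$group)] <- "other"
  groups <- tapply(tab$pct_contribution, tab$group, sum)
  structure(list(baseline_pseudo_r2 = baseline, terms = tab,
                 groups = data.frame(group = names(groups),
                                     pct_contribution = as.numeric(groups),
                                     row.names = NULL)),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf("Variance partition (baseline pseudo-R2 = %.3f)\n",
              x$baseline_pseudo_r2))
  tab <- x$terms[order(-x$terms$pct_contribution),
                 c("term", "pct_contribution", "group")]
  print(utils::head(transform(tab, pct_contribution = round(pct_contribution, 2)), 12),
        row.names = FALSE)
  cat("Groups:\n")
  print(transform(x$groups, pct_contribution = round(pct_contribution, 2)),
        row.names = FALSE)
  invisible(x)
}

#' Marginal effect curves and interaction surfaces
#'
#' Predictions over a grid of a focal continuous term with all other
#' continuous terms at their means, categorical terms at their reference
#' level, and random effects at the population level. For an interaction,
#' the moderator is evaluated at the first and third quartiles of its
#' training values. 95% bands come from the posterior draws of the
#' conditional expectation.
#'
#' @param fit a `movement_fit`.
#' @param focal name of the focal continuous term.
#' @param moderator optional second continuous term evaluated at Q1/Q3.
#' @param n_grid grid resolution along the focal term.
#' @return data.frame: focal value, moderator value and label (when given),
#'   median, lo95, hi95 on the natural response scale.
#' @export
marginal_effects <- function(fit, focal, moderator = NULL, n_grid = 25) {
  stopifnot(inherits(fit, "movement_fit"))
  cont <- setdiff(fit$terms, names(predmove_levels))
  if (!focal %in% cont) stop_predmove("unknown focal term '", focal, "'")
  if (!is.null(moderator) && !moderator %in% cont)
    stop_predmove("unknown moderator term '", moderator, "'")
  rec <- fit$records
  grid_f <- seq(min(rec[[focal]]), max(rec[[focal]]), length.out = n_grid)
  mod_vals <- if (is.null(moderator)) NA else
    quantile_lin(rec[[moderator]], c(0.25, 0.75))
  mod_labs <- if (is.null(moderator)) NA else c("Q1", "Q3")

  proto <- rec[1, , drop = FALSE]
  for (tc in cont) proto[[tc]] <- fit$design$center[[tc]]
  for (cc in names(predmove_levels))
    if (cc %in% fit$terms) proto[[cc]] <- predmove_levels[[cc]][1]
  proto$individual_id <- ".novel_individual_id"
  proto$grid_cell_id <- ".novel_grid_cell_id"

  out <- list()
  for (mi in seq_along(mod_vals)) {
    nd <- proto[rep(1, n_grid), , drop = FALSE]
    nd[[focal]] <- grid_f
    if (!is.null(moderator)) nd[[moderator]] <- mod_vals[mi]
    pd <- posterior_predict(fit, nd, return_draws = TRUE)
    out[[mi]] <- data.frame(
      focal = focal, value = grid_f,
      moderator = if (is.null(moderator)) NA_character_ else moderator,
      moderator_value = mod_vals[mi], moderator_label = mod_labs[mi],
      median = apply(pd, 2, stats::median),
      lo95 = apply(pd, 2, quantile_lin, 0.025),
      hi95 = apply(pd, 2, quantile_lin, 0.975))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
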