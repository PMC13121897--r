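#' Posterior predictions from a movement model
#'
#' Computes, per record, the posterior distribution of the conditional
#' expectation and returns its median (the quantity used for pseudo-R2 and
#' variance partitioning). For the Gaussian square-root models the natural-
#' scale prediction back-transforms the linear predictor by squaring; for the
#' zero-inflated Beta model it is `(1 - pi) * mu`. Predictor overrides allow
#' neutralising terms: a continuous term is set to a supplied value on the
#' data scale (its training mean neutralises it), a categorical term to a
#' level, a random-effect id column to `"new"`, introducing a level absent
#' from the training data whose effect is the population level (0), with the
#' random-SD uncertainty already integrated over the retained draws.
#' Override names containing `:` target an interaction's design columns
#' directly, fixing them at their training means.
#'
#' @param fit a `movement_fit`.
#' @param newdata records to predict for; defaults to the training records.
#' @param overrides named list of term overrides (see Details).
#' @param scale `"natural"` (response scale, default) or `"link"` (the
#'   fitting scale: sqrt km or logit).
#' @param new_level `"zero"` (default) sets effects of unseen random-effect
#'   levels to 0; `"sample"` draws them from N(0, sd) per posterior draw
#'   (seeded for reproducibility).
#' @param return_draws return the full draws x records matrix instead of
#'   per-record medians.
#' @param seed seed used only when `new_level = "sample"`.
#' @return numeric vector of per-record posterior-median predictions (or a
#'   matrix when `return_draws = TRUE`).
#' @export
posterior_predict <- function(fit, newdata = NULL, overrides = list(),
                              scale = c("natural", "link"),
                              new_level = c("zero", "sample"),
                              return_draws = FALSE, seed = 1L) {
  stopifnot(inherits(fit, "movement_fit"))
  scale <- match.arg(scale)
  new_level <- match.arg(new_level)
  rec <- newdata %||% fit$records
  if (is.null(rec)) stop_predmove("no records to predict for (prior-only fit?)")

  known <- c(fit$terms, "individual_id", "grid_cell_id",
             fit$interactions)
  bad <- setdiff(names(overrides), known)
  if (length(bad))
    stop_predmove("override of unknown term(s): ", paste(bad, collapse = ", "))

  ia_over <- intersect(names(overrides), fit$interactions)
  for (nm in setdiff(names(overrides), ia_over)) {
    val <- overrides[[nm]]
    if (nm %in% c("individual_id", "grid_cell_id")) {
      rec[[nm]] <- if (identical(val, "new"))
        paste0(".novel_", nm) else as.character(val)
    } else {
      rec[[nm]] <- val
    }
  }

  des <- build_design(rec, fit$terms, fit$interactions,
                      center = fit$design$center, scale = fit$design$scale)
  X <- des$X[, colnames(fit$design$X), drop = FALSE]
  for (nm in ia_over) {
    cls <- names(fit$design$term_of)[fit$design$term_of == nm]
    for (cl in cls)
      X[, cl] <- mean(fit$design$X[, cl])
  }

  dm <- fit$draws
  B <- dm[, colnames(fit$design$X), drop = FALSE]
  eta <- B %*% t(X)  # draws x records

  add_re <- function(eta, ids, levels, prefix, sd_col) {
    idx <- match(as.character(ids), levels)
    seen <- !is.na(idx)
    if (any(seen)) {
      recols <- paste0(prefix, "[", idx[seen], "]")
      eta[, seen] <- eta[, seen] + dm[, recols, drop = FALSE]
    }
    if (any(!seen) && new_level == "sample") {
      sd_draws <- dm[, sd_col]
      novel <- unique(as.character(ids)[!seen])
      re_nov <- with_seed(seed, vapply(novel, function(z)
        stats::rnorm(length(sd_draws), 0, sd_draws),
        numeric(length(sd_draws))))
      j <- match(as.character(ids)[!seen], novel)
      eta[, !seen] <- eta[, !seen, drop = FALSE] + re_nov[, j, drop = FALSE]
    }
    eta
  }
  eta <- add_re(eta, rec$individual_id, fit$ind_levels, "u", "sigma_u")
  eta <- add_re(eta, rec$grid_cell_id, fit$cell_levels, "v", "sigma_v")

  pred <- if (scale == "link") {
    eta
  } else if (fit$family == "gaussian_sqrt") {
    eta^2
  } else {
    (1 - dm[, "pi"]) * stats::plogis(eta)
  }
  if (return_draws) return(pred)
  apply(pred, 2, stats::median)
}

#' Residuals of a movement model
#'
#' On the fitting scale for the Gaussian models (observed sqrt response minus
#' the posterior-median linear predictor, the scale on which the error model
#' holds); on the response scale for the zero-inflated Beta model.
#'
#' @param object a `movement_fit`.
#' @param ... unused.
#' @return numeric vector aligned with the training records.
#' @export
residuals.movement_fit <- function(object, ...) {
  if (object$family == "gaussian_sqrt") {
    object$y - posterior_predict(object, scale = "link")
  } else {
    object$y - posterior_predict(object, scale = "natural")
  }
}
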