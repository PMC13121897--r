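# Fixed-effect design construction shared by the track simulator (to evaluate
# the true linear predictor) and the model module (to build the fitted design).
# Using one builder guarantees that simulated truth and fitted coefficients
# refer to identical columns.

#' Canonical predictor sets
#'
#' Continuous predictors are the landscape covariates (standardised before
#' modeling); categorical predictors are individual attributes plus the
#' reproductive period. Factor levels are fixed package-wide so that dummy
#' column names are stable: the first level is the treatment reference.
#' @keywords internal
#' @name predictors
NULL

predmove_levels <- list(
  sex = c("F", "M"),
  age = c("adult", "subadult"),
  status = c("pack", "nonpack"),
  period = c("breeding", "mating", "nonreproductive"),
  diet = c("wild", "livestock", "horses")
)

continuous_predictors <- c("pop_density", "settlement_density", "primary_road",
                           "secondary_road", "tri", "refuge_dim1", "refuge_dim2")

#' Default fixed-effect terms and interactions of the movement models
#' @return character vector of main-effect terms / of `"a:b"` interactions.
#' @export
default_terms <- function() {
  c("age", "sex", "status", "period", "diet", continuous_predictors)
}

#' @rdname default_terms
#' @export
default_interactions <- function() {
  c("sex:period", "status:period", "pop_density:settlement_density",
    "primary_road:refuge_dim1", "primary_road:refuge_dim2",
    "secondary_road:refuge_dim1", "secondary_road:refuge_dim2",
    "refuge_dim1:refuge_dim2")
}

# Columns (name -> numeric vector) for one main-effect term.
term_columns <- function(records, term, levels_map) {
  if (term %in% names(levels_map)) {
    lv <- levels_map[[term]]
    f <- factor(as.character(records[[term]]), levels = lv)
    if (anyNA(f))
      stop_predmove("unseen level in '", term, "': ",
                    paste(unique(setdiff(as.character(records[[term]]), lv)), collapse = ", "))
    cols <- lapply(lv[-1], function(l) as.numeric(f == l))
    names(cols) <- paste0(term, lv[-1])
    cols
  } else {
    v <- records[[term]]
    if (is.null(v)) stop_predmove("term '", term, "' not found in records")
    if (!is.numeric(v)) stop_predmove("term '", term, "' must be numeric")
    stats::setNames(list(v), term)
  }
}

#' Build the fixed-effect design matrix
#'
#' Continuous terms are centred and scaled (mean 0, SD 1) using `center` /
#' `scale` when supplied (prediction on new data) or moments computed from
#' `records`. Interaction columns are products of the already-standardised
#' parent columns and are not re-standardised. Categorical terms expand to
#' treatment dummies with package-wide level order.
#'
#' @param records data.frame with one row per daily track.
#' @param terms main-effect term names.
#' @param interactions `"a:b"` interaction names; parents must be in `terms`.
#' @param center,scale named numerics for continuous terms, or NULL to compute.
#' @param standardize set FALSE if continuous columns are already standardised.
#' @return list with `X` (matrix incl. intercept), `center`, `scale`,
#'   `term_of` (named chr: column -> term), `terms`, `interactions`.
#' @export
build_design <- function(records, terms = default_terms(),
                         interactions = default_interactions(),
                         center = NULL, scale = NULL, standardize = TRUE) {
  for (ia in interactions) {
    pr <- strsplit(ia, ":", fixed = TRUE)[[1]]
    if (length(pr) != 2L || !all(pr %in% terms))
      stop_predmove("interaction '", ia, "' must combine two main-effect terms")
  }
  cont <- intersect(terms, continuous_predictors)
  cont <- union(cont, setdiff(terms, names(predmove_levels)))
  if (standardize) {
    if (is.null(center)) center <- vapply(cont, function(t) mean(records[[t]]), 0)
    if (is.null(scale)) {
      scale <- vapply(cont, function(t) stats::sd(records[[t]]), 0)
      if (any(scale == 0))
        stop_predmove("zero-variance continuous predictor(s): ",
                      paste(cont[scale == 0], collapse = ", "))
    }
  } else {
    center <- stats::setNames(rep(0, length(cont)), cont)
    scale <- stats::setNames(rep(1, length(cont)), cont)
  }
  rec <- records
  for (t in cont) rec[[t]] <- (records[[t]] - center[[t]]) / scale[[t]]

  cols <- list(`(Intercept)` = rep(1, nrow(rec)))
  term_of <- c(`(Intercept)` = "(Intercept)")
  blocks <- list()
  for (t in terms) {
    tc <- term_columns(rec, t, predmove_levels)
    blocks[[t]] <- tc
    cols <- c(cols, tc)
    term_of <- c(term_of, stats::setNames(rep(t, length(tc)), names(tc)))
  }
  for (ia in interactions) {
    pr <- strsplit(ia, ":", fixed = TRUE)[[1]]
    for (na in names(blocks[[pr[1]]])) for (nb in names(blocks[[pr[2]]])) {
      nm <- paste0(na, ":", nb)
      cols[[nm]] <- blocks[[pr[1]]][[na]] * blocks[[pr[2]]][[nb]]
      term_of <- c(term_of, stats::setNames(ia, nm))
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, center = center, scale = scale, term_of = term_of,
       terms = terms, interactions = interactions)
}
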