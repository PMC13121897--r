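#' PCA of the five refuge-cover metrics
#'
#' The five refuge metrics are strongly inter-correlated, so the movement
#' models use the first two principal components instead. The PCA is
#' computed on the correlation matrix (metrics standardised to unit
#' variance). Sign conventions are fixed so results are reproducible:
#' dimension 1 loads positively on `refuge_cover_pct` (large, cohesive cover
#' scores high) and dimension 2 loads positively on `mean_fdi` (complex,
#' irregular patch shapes score high).
#'
#' @param covariates data.frame containing the five refuge metric columns.
#' @param metrics the metric column names.
#' @return object of class `refuge_pca`: list with `loadings` (5 x k),
#'   `scores` (n x 2: refuge_dim1, refuge_dim2), `variance_explained`
#'   (fraction per component), `center`, `scale`.
#' @export
refuge_pca <- function(covariates,
                       metrics = c("refuge_cover_pct", "patch_density",
                                   "mean_patch_size", "mean_cohesion",
                                   "mean_fdi")) {
  miss <- setdiff(metrics, names(covariates))
  if (length(miss))
    stop_predmove("missing refuge metric columns: ", paste(miss, collapse = ", "))
  m <- as.matrix(covariates[, metrics])
  if (anyNA(m))
    stop_predmove("refuge metrics contain NA; drop undefined-records first")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop_predmove("zero-variance refuge metric(s): ",
                  paste(metrics[sds == 0], collapse = ", "))
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  # sign conventions
  if (pc$rotation["refuge_cover_pct", 1] < 0) {
    pc$rotation[, 1] <- -pc$rotation[, 1]; pc$x[, 1] <- -pc$x[, 1]
  }
  if (ncol(pc$rotation) >= 2 && pc$rotation["mean_fdi", 2] < 0) {
    pc$rotation[, 2] <- -pc$rotation[, 2]; pc$x[, 2] <- -pc$x[, 2]
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, 1:2, drop = FALSE]
  colnames(scores) <- c("refuge_dim1", "refuge_dim2")
  structure(list(loadings = pc$rotation, scores = scores,
                 variance_explained = ve, center = pc$center,
                 scale = pc$scale, metrics = metrics),
            class = "refuge_pca")
}

#' @export
print.refuge_pca <- function(x, ...) {
  cat("Refuge-cover PCA:",
      sprintf("dim1 %.1f%%, dim2 %.1f%% of variance\n",
              100 * x$variance_explained[1], 100 * x$variance_explained[2]))
  print(round(x$loadings[, 1:2, drop = FALSE], 3))
  invisible(x)
}

#' Append refuge PCA scores to a covariate table
#'
#' @param covariates covariate records containing the five refuge metrics.
#' @param pca a [refuge_pca()]; when NULL it is computed from `covariates`.
#' @return `covariates` with `refuge_dim1` / `refuge_dim2` columns; the PCA
#'   object is attached as attribute `"refuge_pca"`.
#' @export
add_refuge_dims <- function(covariates, pca = NULL) {
  if (is.null(pca)) pca <- refuge_pca(covariates)
  m <- scale(as.matrix(covariates[, pca$metrics]), pca$center, pca$scale)
  sc <- m %*% pca$loadings[, 1:2, drop = FALSE]
  covariates$refuge_dim1 <- sc[, 1]
  covariates$refuge_dim2 <- sc[, 2]
  attr(covariates, "refuge_pca") <- pca
  covariates
}
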