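#' Simulate records directly from the zero-inflated Beta straightness model
#'
#' Bypasses the movement simulator: draws a straightness-like response from
#' the exact likelihood the straightness model fits, for calibration and
#' recovery checks of the zero-inflated Beta machinery. Covariates are
#' standard normal under their canonical names.
#'
#' @param n number of records.
#' @param beta named coefficients on the logit scale (see [truth_table()]
#'   naming); must include `"(Intercept)"`.
#' @param phi Beta precision.
#' @param pi zero-inflation probability.
#' @param sigma_individual,sigma_cell random-intercept SDs.
#' @param n_individuals,n_cells numbers of random-effect levels.
#' @param covariates continuous covariate names to generate.
#' @param seed integer seed.
#' @return data.frame with `straightness`, covariates, `individual_id`,
#'   `grid_cell_id`, `track_date` and attribute columns at reference levels.
#' @export
simulate_zib_records <- function(n, beta = c("(Intercept)" = -0.3, tri = 0.6),
                                 phi = 8, pi = 0.10,
                                 sigma_individual = 0, sigma_cell = 0,
                                 n_individuals = 10, n_cells = 25,
                                 covariates = intersect(names(beta),
                                                        continuous_predictors),
                                 seed = 1L) {
  with_seed(seed, {
    rec <- data.frame(individual_id = sample(sprintf("ind%02d", seq_len(n_individuals)),
                                             n, TRUE),
                      grid_cell_id = sample(sprintf("c%03d", seq_len(n_cells)),
                                            n, TRUE),
                      track_date = as.Date("2010-01-01") + seq_len(n) %% 360)
    for (cv in covariates) rec[[cv]] <- stats::rnorm(n)
    for (cc in names(predmove_levels)) rec[[cc]] <- predmove_levels[[cc]][1]
    rec$period <- assign_period(rec$track_date)
    parsed <- parse_truth_terms(beta, covariates)
    u <- stats::rnorm(n_individuals, 0, sigma_individual)
    v <- stats::rnorm(n_cells, 0, sigma_cell)
    eta <- vapply(seq_len(n), function(i) {
      covs <- as.list(rec[i, covariates, drop = FALSE])
      eval_lp(parsed, beta, covs,
              as.list(rec[i, names(predmove_levels), drop = FALSE]))
    }, 0)
    eta <- eta + u[match(rec$individual_id, sort(unique(rec$individual_id)))] +
      v[match(rec$grid_cell_id, sort(unique(rec$grid_cell_id)))]
    mu <- stats::plogis(eta)
    y <- stats::rbeta(n, mu * phi, (1 - mu) * phi)
    y[stats::runif(n) < pi] <- 0
    rec$straightness <- y
    rec
  })
}

#' Configuration of an end-to-end pipeline run
#'
#' @param landscape a [landscape_config()].
#' @param sim a [sim_config()].
#' @param truth a [truth_table()].
#' @param responses which movement metrics to model.
#' @param buffer_radius_km,kernel_bandwidth_km covariate extraction settings.
#' @param subsample_seed seed of the stratified 2/3 subsample.
#' @param chains,iter,warmup MCMC settings shared by all models.
#' @param covariate_source `"extracted"` runs the full influence-area
#'   extraction; `"simulated"` reuses the simulator's per-day covariates
#'   (fast; skips the PCA since the simulator emits the refuge dimensions
#'   directly).
#' @param seed master seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(landscape = landscape_config(),
                       sim = sim_config(),
                       truth = default_truth(),
                       responses = c("daily_distance", "net_displacement",
                                     "straightness"),
                       buffer_radius_km = 1, kernel_bandwidth_km = 1,
                       subsample_seed = 1L,
                       chains = 4, iter = 4000, warmup = 2000,
                       covariate_source = c("extracted", "simulated"),
                       seed = 1L) {
  covariate_source <- match.arg(covariate_source)
  structure(list(landscape = landscape, sim = sim, truth = truth,
                 responses = responses,
                 buffer_radius_km = buffer_radius_km,
                 kernel_bandwidth_km = kernel_bandwidth_km,
                 subsample_seed = subsample_seed, chains = chains,
                 iter = iter, warmup = warmup,
                 covariate_source = covariate_source,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full movement-analysis pipeline on synthetic data
#'
#' Stages: landscape generation, track simulation, daily-track segmentation
#' and the completeness filter, movement metrics, covariate extraction (or
#' reuse of simulated covariates), refuge PCA, 2/3 stratified subsampling,
#' model fitting per response, Probability of Direction, variance
#' partitioning, and diagnostics. Every record-count change is logged in the
#' manifest. When `outdir` is given, all artifact tables are written as
#' CSV/JSON.
#'
#' @param config a [run_config()].
#' @param outdir optional output directory.
#' @param verbose print stage progress.
#' @return object of class `pipeline_result`: list with `landscape`,
#'   `tracks`, `metrics`, `summary_table`, `covariates`, `pca`, `records`,
#'   `fits`, `pd`, `partitions`, `diagnostics`, `manifest`.
#' @export
run_pipeline <- function(config, outdir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(...)
  manifest <- list(seed = config$seed,
                   r_version = as.character(getRversion()),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  say("stage 1/7: landscape")
  landscape <- generate_landscape(config$landscape)

  say("stage 2/7: track simulation")
  tracks <- simulate_tracks(landscape, config$sim, config$truth)
  manifest$n_fixes <- nrow(tracks$fixes)
  manifest$n_days_simulated <- nrow(tracks$days)

  say("stage 3/7: segmentation + completeness filter")
  dt <- segment_days(tracks$fixes)
  manifest$n_tracks_segmented <- nrow(dt$tracks)
  dtf <- filter_complete(dt)
  manifest$n_tracks_retained <- attr(dtf, "n_retained")
  manifest$n_tracks_dropped <- attr(dtf, "n_dropped")

  say("stage 4/7: movement metrics")
  metrics <- track_metrics(dtf)
  summary_table <- summarize_metrics(metrics)

  say("stage 5/7: covariates (", config$covariate_source, ")")
  if (config$covariate_source == "extracted") {
    covariates <- extract_covariates(dtf, landscape, tracks$attributes,
                                     radius_km = config$buffer_radius_km,
                                     bandwidth_km = config$kernel_bandwidth_km,
                                     verbose = verbose)
    ok <- stats::complete.cases(covariates[, c("mean_patch_size",
                                               "mean_cohesion", "mean_fdi")])
    manifest$n_records_refuge_defined <- sum(ok)
    manifest$n_records_refuge_undefined <- sum(!ok)
    covariates <- covariates[ok, , drop = FALSE]
    pca <- refuge_pca(covariates)
    covariates <- add_refuge_dims(covariates, pca)
  } else {
    covariates <- tracks$days
    covariates$track_id <- paste0(covariates$individual_id, "_",
                                  covariates$track_date)
    pca <- NULL
    manifest$n_records_refuge_defined <- nrow(covariates)
    manifest$n_records_refuge_undefined <- 0L
  }
  records <- merge(covariates,
                   metrics[, c("track_id", "daily_distance_km",
                               "net_displacement_km", "straightness")],
                   by = "track_id")
  manifest$n_records_modeling <- nrow(records)

  say("stage 6/7: subsample + model fits")
  records <- subsample_two_thirds(records, seed = config$subsample_seed)
  manifest$n_records_subsampled <- nrow(records)

  standardize <- config$covariate_source == "extracted"
  fits <- list(); pd <- list(); partitions <- list(); diags <- list()
  for (resp in config$responses) {
    say("  fitting ", resp)
    fits[[resp]] <- fit_movement_model(
      records, response = resp, chains = config$chains, iter = config$iter,
      warmup = config$warmup, standardize = standardize, seed = config$seed)
    pd[[resp]] <- probability_of_direction(fits[[resp]])
    partitions[[resp]] <- variance_partition(fits[[resp]])
    diags[[resp]] <- diagnose_fit(fits[[resp]], seed = config$seed)
  }

  say("stage 7/7: artifacts")
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  out <- structure(list(landscape = landscape, tracks = tracks,
                        metrics = metrics, summary_table = summary_table,
                        covariates = covariates, pca = pca, records = records,
                        fits = fits, pd = pd, partitions = partitions,
                        diagnostics = diags, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline(out, outdir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("Pipeline run:", m$n_fixes, "fixes ->", m$n_tracks_segmented,
      "tracks ->", m$n_tracks_retained, "complete ->",
      m$n_records_subsampled, "modeled records\n")
  for (r in names(x$fits))
    cat(sprintf("  %s: pseudo-R2 %.3f, max rhat %.3f\n", r,
                x$partitions[[r]]$baseline_pseudo_r2,
                x$diagnostics[[r]]$rhat_max))
  invisible(x)
}

#' Write all pipeline artifacts to a directory
#' @param result a `pipeline_result`.
#' @param outdir output directory (created).
#' @return invisibly, `outdir`.
#' @export
write_pipeline <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.csv(df, file.path(outdir, name),
                                           row.names = FALSE)
  w(result$metrics, "metrics.csv")
  w(result$summary_table, "metrics_summary.csv")
  w(result$covariates, "covariates.csv")
  if (!is.null(result$pca)) {
    w(data.frame(metric = rownames(result$pca$loadings),
                 result$pca$loadings, check.names = FALSE), "pca_loadings.csv")
  }
  for (r in names(result$fits)) {
    write_fit(result$fits[[r]], outdir)
    w(result$pd[[r]], paste0(r, "_pd.csv"))
    w(result$partitions[[r]]$terms, paste0(r, "_variance_partition.csv"))
    jsonlite::write_json(
      list(rhat_max = result$diagnostics[[r]]$rhat_max,
           morans_i = result$diagnostics[[r]]$morans_i,
           acf = result$diagnostics[[r]]$acf,
           ppc = result$diagnostics[[r]]$ppc),
      file.path(outdir, paste0(r, "_diagnostics.json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
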