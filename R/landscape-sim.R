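#' Configuration for a synthetic landscape
#'
#' Describes a planar rectangular landscape in km with a binary refuge raster,
#' an elevation raster, weighted settlement points and classified road lines.
#' Defaults emulate a heavily anthropised Atlantic study region: about 3
#' settlements per km2, 3.5 km/km2 of paved roads (split into primary and
#' secondary classes), roughly half the area under vegetation that can act as
#' refuge, and a heavy-tailed settlement population distribution.
#'
#' All coordinates are planar km; users with real data must pre-project to a
#' metric CRS. Rasters use `raster_resolution_m` (default 10 m) cells.
#'
#' @param extent_km width and height of the landscape in km (length-2 positive).
#' @param raster_resolution_m raster cell size in metres; must divide both
#'   extents exactly.
#' @param settlements_per_km2 mean density of settlement points.
#' @param population_meanlog,population_sdlog log-normal parameters of
#'   settlement population sizes (heavy-tailed, rounded up to >= 1 inhabitant).
#' @param road_km_per_km2 named nonnegative vector `c(primary=, secondary=)`
#'   of target road length densities.
#' @param refuge_target_cover target refuge cover fraction in \[0, 1\].
#' @param refuge_patchiness_m smoothing length (m) of the latent field whose
#'   thresholding produces refuge patches; larger values give larger patches.
#' @param elevation_relief_m total elevation range (m).
#' @param elevation_smoothness_m smoothing length (m) of the elevation field.
#' @param seed integer seed; the whole landscape is a deterministic function
#'   of the configuration.
#' @return An object of class `landscape_config`.
#' @export
landscape_config <- function(extent_km = c(20, 20),
                             raster_resolution_m = 10,
                             settlements_per_km2 = 3,
                             population_meanlog = log(40),
                             population_sdlog = 1.3,
                             road_km_per_km2 = c(primary = 0.5, secondary = 3),
                             refuge_target_cover = 0.5,
                             refuge_patchiness_m = 300,
                             elevation_relief_m = 600,
                             elevation_smoothness_m = 2000,
                             seed = 1L) {
  if (length(extent_km) != 2L || any(!is.finite(extent_km)) || any(extent_km <= 0))
    stop_predmove("extent_km must be two positive numbers")
  if (raster_resolution_m <= 0)
    stop_predmove("raster_resolution_m must be positive")
  res_km <- raster_resolution_m / 1000
  n_cells <- extent_km / res_km
  if (any(abs(n_cells - round(n_cells)) > 1e-8))
    stop_predmove("raster_resolution_m must divide both extents exactly")
  if (refuge_target_cover < 0 || refuge_target_cover > 1)
    stop_predmove("refuge_target_cover must lie in [0, 1]")
  if (!all(c("primary", "secondary") %in% names(road_km_per_km2)))
    stop_predmove("road_km_per_km2 needs named entries 'primary' and 'secondary'")
  if (any(road_km_per_km2 < 0) || settlements_per_km2 < 0 ||
      elevation_relief_m < 0 || refuge_patchiness_m <= 0)
    stop_predmove("densities and relief must be nonnegative; patchiness positive")
  structure(list(
    extent_km = as.numeric(extent_km),
    raster_resolution_m = raster_resolution_m,
    settlements_per_km2 = settlements_per_km2,
    population_meanlog = population_meanlog,
    population_sdlog = population_sdlog,
    road_km_per_km2 = road_km_per_km2[c("primary", "secondary")],
    refuge_target_cover = refuge_target_cover,
    refuge_patchiness_m = refuge_patchiness_m,
    elevation_relief_m = elevation_relief_m,
    elevation_smoothness_m = elevation_smoothness_m,
    seed = as.integer(seed)
  ), class = "landscape_config")
}

#' Generate a synthetic landscape
#'
#' Realises a [landscape_config()] into rasters and vector layers. The refuge
#' raster is produced by thresholding a smoothed Gaussian noise field at the
#' quantile that yields the target cover, giving contiguous patches whose
#' typical size is controlled by `refuge_patchiness_m`. Roads are random
#' straight chords accumulated (last one trimmed) until the target length
#' density per class is met exactly. Settlement positions are uniform with
#' log-normal population weights. Deterministic under the config seed.
#'
#' Raster matrices are indexed `[row, col]` with row r covering
#' y in ((r-1), r\] * resolution and col c covering x likewise; cell centres
#' are at ((c-0.5)*res, (r-0.5)*res) km.
#'
#' @param config a [landscape_config()].
#' @return An object of class `landscape`: a list with `refuge` (binary
#'   matrix), `elevation` (matrix, m), `settlements` (data.frame `x_km`,
#'   `y_km`, `population`), `roads` (data.frame `road_id`, `class`, `x0`,
#'   `y0`, `x1`, `y1` in km), `extent_km`, `res_km`, and the config.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  with_seed(config$seed, {
    res_km <- config$raster_resolution_m / 1000
    nc <- round(config$extent_km[1] / res_km)
    nr <- round(config$extent_km[2] / res_km)
    area <- prod(config$extent_km)

    # refuge: threshold smoothed white noise at the cover quantile
    if (config$refuge_target_cover == 0) {
      refuge <- matrix(0L, nr, nc)
    } else if (config$refuge_target_cover == 1) {
      refuge <- matrix(1L, nr, nc)
    } else {
      field <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc),
                            config$refuge_patchiness_m / config$raster_resolution_m)
      thr <- quantile_lin(field, 1 - config$refuge_target_cover)
      refuge <- matrix(as.integer(field > thr), nr, nc)
    }

    # elevation: smoothed noise rescaled to the requested relief
    ef <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc),
                       config$elevation_smoothness_m / config$raster_resolution_m)
    rng <- range(ef)
    elevation <- if (diff(rng) > 0) {
      (ef - rng[1]) / diff(rng) * config$elevation_relief_m
    } else {
      matrix(0, nr, nc)
    }

    # settlements: uniform points, heavy-tailed integer populations
    n_set <- round(config$settlements_per_km2 * area)
    settlements <- data.frame(
      x_km = stats::runif(n_set, 0, config$extent_km[1]),
      y_km = stats::runif(n_set, 0, config$extent_km[2]),
      population = pmax(1, round(stats::rlnorm(n_set, config$population_meanlog,
                                               config$population_sdlog)))
    )

    roads <- make_roads(config$road_km_per_km2, config$extent_km)
    structure(list(refuge = refuge, elevation = elevation,
                   settlements = settlements, roads = roads,
                   extent_km = config$extent_km, res_km = res_km,
                   config = config),
              class = "landscape")
  })
}

# Random straight chords through the extent, accumulated per class until the
# target total length is reached; the final chord is trimmed so the realised
# density matches the target exactly.
make_roads <- function(road_km_per_km2, extent_km) {
  out <- list()
  id <- 0L
  for (cls in names(road_km_per_km2)) {
    target <- road_km_per_km2[[cls]] * prod(extent_km)
    if (target <= 0) next
    total <- 0
    guard <- 0L
    while (total < target) {
      guard <- guard + 1L
      if (guard > 100000L)
        stop_predmove("road generation failed to reach target density (infeasible target)")
      px <- stats::runif(1, 0, extent_km[1]); py <- stats::runif(1, 0, extent_km[2])
      th <- stats::runif(1, 0, pi)
      dx <- cos(th); dy <- sin(th)
      # parametric clip of the infinite line to the extent
      ts <- c(if (dx != 0) c((0 - px) / dx, (extent_km[1] - px) / dx),
              if (dy != 0) c((0 - py) / dy, (extent_km[2] - py) / dy))
      pts_t <- sort(ts)
      inside <- pts_t[sapply(pts_t, function(t) {
        x <- px + t * dx; y <- py + t * dy
        x >= -1e-9 && x <= extent_km[1] + 1e-9 && y >= -1e-9 && y <= extent_km[2] + 1e-9
      })]
      if (length(inside) < 2) next
      t0 <- min(inside); t1 <- max(inside)
      len <- t1 - t0
      if (len < 1e-6) next
      if (total + len > target) {  # trim the last chord
        len_keep <- target - total
        t1 <- t0 + len_keep
        len <- len_keep
      }
      id <- id + 1L
      out[[id]] <- data.frame(road_id = id, class = cls,
                              x0 = px + t0 * dx, y0 = py + t0 * dy,
                              x1 = px + t1 * dx, y1 = py + t1 * dy)
      total <- total + len
    }
  }
  if (length(out) == 0) {
    return(data.frame(road_id = integer(), class = character(),
                      x0 = numeric(), y0 = numeric(),
                      x1 = numeric(), y1 = numeric()))
  }
  do.call(rbind, out)
}

#' @export
print.landscape <- function(x, ...) {
  cat("Synthetic landscape:", paste(x$extent_km, collapse = " x "), "km,",
      nrow(x$refuge), "x", ncol(x$refuge), "cells at",
      x$config$raster_resolution_m, "m\n")
  cat("  refuge cover:", sprintf("%.1f%%", 100 * mean(x$refuge)), "\n")
  cat("  settlements:", nrow(x$settlements), "\n")
  rl <- road_lengths(x$roads)
  cat("  road density (km/km2):",
      paste(sprintf("%s %.2f", names(rl), rl / prod(x$extent_km)), collapse = ", "), "\n")
  invisible(x)
}

road_lengths <- function(roads) {
  if (nrow(roads) == 0) return(c(primary = 0, secondary = 0))
  len <- sqrt((roads$x1 - roads$x0)^2 + (roads$y1 - roads$y0)^2)
  tapply(len, roads$class, sum)
}

#' Write a landscape to plain-text files
#'
#' Rasters go to Esri ASCII grid (`.asc`), settlements and roads to GeoJSON,
#' all in the planar km coordinate system of the landscape.
#'
#' @param landscape a `landscape`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    refuge = file.path(dir, "refuge.asc"),
    elevation = file.path(dir, "elevation.asc"),
    settlements = file.path(dir, "settlements.geojson"),
    roads = file.path(dir, "roads.geojson")
  )
  write_ascii_grid(landscape$refuge, paths["refuge"], landscape$res_km)
  write_ascii_grid(landscape$elevation, paths["elevation"], landscape$res_km)
  write_geojson_points(landscape$settlements, paths["settlements"])
  write_geojson_roads(landscape$roads, paths["roads"])
  invisible(paths)
}

# Esri ASCII grid; rows written north-to-south per the format convention.
write_ascii_grid <- function(m, path, res_km) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    "xllcorner 0", "yllcorner 0",
    paste("cellsize", res_km), "NODATA_value -9999"
  ), con)
  for (r in rev(seq_len(nrow(m))))
    writeLines(paste(m[r, ], collapse = " "), con)
  invisible(path)
}

#' Read an Esri ASCII grid written by [write_ascii_grid()]
#' @param path file path.
#' @return list with `matrix` (row 1 = southernmost band) and `cellsize`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  vals <- stats::setNames(as.numeric(vapply(hdr, `[`, "", 2)),
                          vapply(hdr, `[`, "", 1))
  body <- lapply(lines[-(1:6)], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, body)
  list(matrix = m[rev(seq_len(nrow(m))), , drop = FALSE], cellsize = vals[["cellsize"]])
}

write_geojson_points <- function(df, path) {
  feats <- lapply(seq_len(nrow(df)), function(i) list(
    type = "Feature",
    geometry = list(type = "Point", coordinates = c(df$x_km[i], df$y_km[i])),
    properties = list(population = df$population[i])
  ))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
}

write_geojson_roads <- function(df, path) {
  feats <- lapply(seq_len(nrow(df)), function(i) list(
    type = "Feature",
    geometry = list(type = "LineString",
                    coordinates = list(c(df$x0[i], df$y0[i]), c(df$x1[i], df$y1[i]))),
    properties = list(road_id = df$road_id[i], class = df$class[i])
  ))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
}
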