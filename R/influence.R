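# Covariate extraction inside 1-km influence areas around daily tracks.
# All geometry is planar km. Influence areas are represented as raster masks
# aligned to the landscape grid: a cell belongs to the area when its centre
# lies within the buffer radius of the track polyline. Road lengths are
# clipped against the exact buffer (distance to the polyline), not the mask.

#' Buffer a daily track into its influence area
#'
#' The influence area is the set of points within `radius_km` of the polyline
#' through the track's fixes (a disk for a single-fix track), discretised on
#' a grid of `res_km` cells aligned to the landscape origin. The polygon area
#' is estimated as cell count times cell area; at the default 10-m grid the
#' relative error is well below 0.5%.
#'
#' @param track data.frame of one track's fixes ordered by time (`x_km`,
#'   `y_km`), or a list with those columns.
#' @param radius_km buffer radius (default 1 km).
#' @param res_km grid resolution in km (default 0.01 = 10 m).
#' @return object of class `influence_area`: list with `vx`, `vy` (polyline),
#'   `radius_km`, `res_km`, `rows`, `cols` (grid index ranges), `mask`
#'   (logical matrix `length(rows)` x `length(cols)`), `area_km2`.
#' @export
buffer_track <- function(track, radius_km = 1, res_km = 0.01) {
  vx <- track$x_km; vy <- track$y_km
  if (length(vx) < 1L) stop_predmove("track needs at least one fix")
  c0 <- max(1L, floor((min(vx) - radius_km) / res_km) + 1L)
  c1 <- ceiling((max(vx) + radius_km) / res_km)
  r0 <- max(1L, floor((min(vy) - radius_km) / res_km) + 1L)
  r1 <- ceiling((max(vy) + radius_km) / res_km)
  cols <- c0:c1; rows <- r0:r1
  xc <- (cols - 0.5) * res_km
  yc <- (rows - 0.5) * res_km
  pts_x <- rep(xc, each = length(yc))
  pts_y <- rep(yc, times = length(xc))
  d <- dist_to_polyline(pts_x, pts_y, vx, vy)
  mask <- matrix(d <= radius_km, nrow = length(rows), ncol = length(cols))
  structure(list(vx = vx, vy = vy, radius_km = radius_km, res_km = res_km,
                 rows = rows, cols = cols, mask = mask,
                 area_km2 = sum(mask) * res_km^2),
            class = "influence_area")
}

#' Quartic kernel density surface of weighted settlement points
#'
#' The quartic (Epanechnikov-squared) kernel
#' `K(d) = 3/(pi h^2) (1 - d^2/h^2)^2` for `d < h`, the kernel used by
#' standard GIS kernel-density tools, is summed over points with the given
#' weights, so the surface integrates to the total weight. Evaluated on the
#' landscape raster grid (or any grid defined by `extent_km`/`res_km`).
#'
#' @param settlements data.frame with `x_km`, `y_km` (and optionally
#'   `population`).
#' @param weights numeric weights per point; defaults to `population` when
#'   present, else 1 (the unweighted variant used for settlement density).
#' @param bandwidth_km kernel bandwidth h (> 0); default 1 km.
#' @param extent_km landscape extent `c(width, height)`.
#' @param res_km evaluation grid resolution.
#' @return density matrix (weight per km2), rows = y bands, cols = x bands.
#' @export
settlement_kernel_density <- function(settlements, weights = NULL,
                                      bandwidth_km = 1, extent_km,
                                      res_km = 0.01) {
  if (bandwidth_km <= 0) stop_predmove("bandwidth must be positive")
  if (is.null(weights))
    weights <- settlements$population %||% rep(1, nrow(settlements))
  if (length(weights) == 1L) weights <- rep(weights, nrow(settlements))
  xc <- seq(res_km / 2, extent_km[1] - res_km / 2, by = res_km)
  yc <- seq(res_km / 2, extent_km[2] - res_km / 2, by = res_km)
  kernel_density_grid(settlements$x_km, settlements$y_km, weights,
                      bandwidth_km, xc, yc)
}

#' Road length density inside an influence area
#'
#' Clips road polylines of one class against the exact buffer (points within
#' the radius of the track polyline, tested on a 1-m densification of each
#' road segment) and divides the clipped length by the area of the influence
#' area.
#'
#' @param roads data.frame of segments (`class`, `x0`, `y0`, `x1`, `y1`).
#' @param area an [buffer_track()] `influence_area`.
#' @param road_class `"primary"` or `"secondary"` (must appear in the data's
#'   class vocabulary).
#' @return density in km/km2.
#' @export
road_density <- function(roads, area, road_class) {
  stopifnot(inherits(area, "influence_area"))
  if (!road_class %in% c("primary", "secondary"))
    stop_predmove("unknown road class '", road_class, "'")
  seg <- roads[roads$class == road_class, , drop = FALSE]
  if (nrow(seg) == 0) return(0)
  step <- 0.001
  total <- 0
  for (i in seq_len(nrow(seg))) {
    len <- sqrt((seg$x1[i] - seg$x0[i])^2 + (seg$y1[i] - seg$y0[i])^2)
    if (len == 0) next
    # quick reject: segment bbox vs. buffer bbox
    if (max(seg$x0[i], seg$x1[i]) < min(area$vx) - area$radius_km ||
        min(seg$x0[i], seg$x1[i]) > max(area$vx) + area$radius_km ||
        max(seg$y0[i], seg$y1[i]) < min(area$vy) - area$radius_km ||
        min(seg$y0[i], seg$y1[i]) > max(area$vy) + area$radius_km) next
    n <- max(1L, ceiling(len / step))
    t <- (seq_len(n) - 0.5) / n
    px <- seg$x0[i] + t * (seg$x1[i] - seg$x0[i])
    py <- seg$y0[i] + t * (seg$y1[i] - seg$y0[i])
    inside <- dist_to_polyline(px, py, area$vx, area$vy) <= area$radius_km
    total <- total + sum(inside) * (len / n)
  }
  total / area$area_km2
}

#' Terrain Ruggedness Index raster
#'
#' Riley's TRI: per cell, the square root of the summed squared elevation
#' differences to its eight neighbours. Edge cells use the neighbours that
#' exist.
#'
#' @param elevation elevation matrix (any units; TRI inherits them).
#' @return matrix of the same dimensions.
#' @export
terrain_ruggedness <- function(elevation) {
  nr <- nrow(elevation); nc <- ncol(elevation)
  if (nr < 3L || nc < 3L) stop_predmove("elevation raster must be at least 3x3")
  acc <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    diff2 <- (elevation[which(ok_r), which(ok_c), drop = FALSE] -
                elevation[rs[ok_r], cs[ok_c], drop = FALSE])^2
    acc[which(ok_r), which(ok_c)] <- acc[which(ok_r), which(ok_c)] + diff2
  }
  sqrt(acc)
}

#' Label refuge patches inside an influence area
#'
#' Connected components of refuge cells under 8-connectivity (diagonal
#' touching joins patches; FRAGSTATS default), optionally clipped to an
#' influence-area mask first. Per patch: cell count, area, and perimeter
#' counted as cell edges adjacent to non-patch cells (including the clip
#' boundary).
#'
#' @param refuge binary matrix (1 = refuge).
#' @param area optional `influence_area` whose mask clips the raster; its
#'   `rows`/`cols` index into `refuge`.
#' @param connectivity 8 (default) or 4.
#' @param cell_km cell side length in km (default 0.01 = 10 m).
#' @return data.frame: patch_id, cell_count, area_km2, perimeter_edges,
#'   perimeter_km. Zero rows when no refuge cell is present.
#' @export
label_patches <- function(refuge, area = NULL, connectivity = 8,
                          cell_km = 0.01) {
  if (!connectivity %in% c(4, 8)) stop_predmove("connectivity must be 4 or 8")
  if (!is.null(area)) {
    stopifnot(inherits(area, "influence_area"))
    rows <- area$rows[area$rows <= nrow(refuge)]
    cols <- area$cols[area$cols <= ncol(refuge)]
    sub <- refuge[rows, cols, drop = FALSE]
    sub[!area$mask[seq_along(rows), seq_along(cols), drop = FALSE]] <- 0L
    cell_km <- area$res_km
  } else {
    sub <- refuge
  }
  nr <- nrow(sub); nc <- ncol(sub)
  idx <- which(sub == 1)
  if (length(idx) == 0)
    return(data.frame(patch_id = integer(), cell_count = integer(),
                      area_km2 = numeric(), perimeter_edges = integer(),
                      perimeter_km = numeric()))
  vid <- integer(nr * nc)
  vid[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- list()
  rook_pairs <- 0L
  for (o in offs) {
    r2 <- r + o[1]; c2 <- c + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- idx[ok]; j2 <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- vid[j2] > 0L
    if (any(hit)) edges[[length(edges) + 1L]] <- cbind(vid[j][hit], vid[j2][hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership

  # perimeter: 4 edges per cell minus 2 per rook-adjacent same-patch pair
  perim <- 4L * tabulate(comp)
  for (o in list(c(1L, 0L), c(0L, 1L))) {
    r2 <- r + o[1]; c2 <- c + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- idx[ok]; j2 <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- vid[j2] > 0L
    pr <- comp[vid[j][hit]]  # rook neighbours are always in the same patch
    if (length(pr)) perim <- perim - 2L * tabulate(pr, nbins = length(perim))
  }
  counts <- tabulate(comp)
  data.frame(patch_id = seq_along(counts), cell_count = counts,
             area_km2 = counts * cell_km^2,
             perimeter_edges = perim, perimeter_km = perim * cell_km)
}

#' The five refuge-cover metrics of an influence area
#'
#' * `refuge_cover_pct`: percentage of the influence area covered by refuge.
#' * `patch_density`: patches per km2.
#' * `mean_patch_size`: mean patch area (km2).
#' * `mean_cohesion`: FRAGSTATS patch cohesion over the area's cells,
#'   reported on \[0, 1\] (the FRAGSTATS value divided by 100); 0 for a
#'   single isolated cell.
#' * `mean_fdi`: mean per-patch fractal dimension index
#'   `2 ln(0.25 P) / ln(A)` with perimeter P in cell edges and area A in
#'   cells; single-cell patches are assigned 1 (a square has FDI exactly 1).
#'   Values are clipped to \[1, 2\] and the number of clipped patches is
#'   reported as attribute `fdi_clipped`.
#'
#' With zero patches, cover and density are 0 and the remaining metrics `NA`.
#'
#' @param patches data.frame from [label_patches()].
#' @param area the `influence_area` the patches were clipped to.
#' @return one-row data.frame of the five metrics.
#' @export
refuge_metrics <- function(patches, area) {
  stopifnot(inherits(area, "influence_area"))
  n <- nrow(patches)
  if (n == 0) {
    out <- data.frame(refuge_cover_pct = 0, patch_density = 0,
                      mean_patch_size = NA_real_, mean_cohesion = NA_real_,
                      mean_fdi = NA_real_)
    attr(out, "fdi_clipped") <- 0L
    return(out)
  }
  total_cells <- sum(area$mask)
  cover <- 100 * sum(patches$cell_count) / total_cells
  dens <- n / area$area_km2
  msize <- mean(patches$area_km2)

  p <- patches$perimeter_edges; a <- patches$cell_count
  cohesion <- if (total_cells > 1) {
    (1 - sum(p) / sum(p * sqrt(a))) / (1 - 1 / sqrt(total_cells))
  } else 0
  fdi <- ifelse(a == 1, 1, 2 * log(0.25 * p) / log(a))
  clipped <- sum(fdi < 1 | fdi > 2)
  fdi <- pmin(2, pmax(1, fdi))
  out <- data.frame(refuge_cover_pct = cover, patch_density = dens,
                    mean_patch_size = msize, mean_cohesion = cohesion,
                    mean_fdi = mean(fdi))
  attr(out, "fdi_clipped") <- as.integer(clipped)
  out
}

#' Assign each track to a 1x1 km grid cell
#'
#' Cells of an axis-aligned 1-km lattice over the landscape; a track belongs
#' to the cell containing its mid-coordinates (midpoint of the coordinate
#' ranges of its fixes).
#'
#' @param fixes data.frame of fixes with `track_id`, `x_km`, `y_km`.
#' @return data.frame `track_id`, `grid_cell_id`.
#' @export
assign_grid_cells <- function(fixes) {
  sp <- split(fixes, fixes$track_id)
  data.frame(
    track_id = names(sp),
    grid_cell_id = vapply(sp, function(f) {
      paste0(floor((min(f$x_km) + max(f$x_km)) / 2), "_",
             floor((min(f$y_km) + max(f$y_km)) / 2))
    }, ""),
    stringsAsFactors = FALSE)
}

#' Extract all per-track covariates from a landscape
#'
#' For every daily track: builds the 1-km influence area, averages the
#' population and settlement kernel-density surfaces and the TRI raster over
#' it, clips road classes against it, computes the five refuge metrics, and
#' attaches the reproductive period (from the track date), the 1-km grid
#' cell, and the individual's attributes.
#'
#' @param dt a `daily_tracks` object (after [filter_complete()]).
#' @param landscape a `landscape`.
#' @param attributes per-individual attribute data.frame (individual_id,
#'   sex, age, status, diet).
#' @param radius_km influence-area radius.
#' @param bandwidth_km kernel bandwidth for the settlement surfaces.
#' @param settlement_variant `"kernel"` (unweighted kernel surface, default)
#'   or `"count"` (raw points inside the buffer over its area) for the
#'   settlement-density covariate.
#' @param verbose print progress every 200 tracks.
#' @return data.frame of covariate records, one row per track.
#' @export
extract_covariates <- function(dt, landscape, attributes, radius_km = 1,
                               bandwidth_km = 1,
                               settlement_variant = c("kernel", "count"),
                               verbose = FALSE) {
  stopifnot(inherits(dt, "daily_tracks"), inherits(landscape, "landscape"))
  settlement_variant <- match.arg(settlement_variant)
  res_km <- landscape$res_km
  pop_surface <- settlement_kernel_density(
    landscape$settlements, weights = landscape$settlements$population,
    bandwidth_km = bandwidth_km, extent_km = landscape$extent_km, res_km = res_km)
  set_surface <- settlement_kernel_density(
    landscape$settlements, weights = rep(1, nrow(landscape$settlements)),
    bandwidth_km = bandwidth_km, extent_km = landscape$extent_km, res_km = res_km)
  tri_surface <- terrain_ruggedness(landscape$elevation)

  fx <- dt$fixes[order(dt$fixes$individual_id, dt$fixes$timestamp), , drop = FALSE]
  by_track <- split(fx, fx$track_id)
  grid_map <- assign_grid_cells(fx)

  rows <- vector("list", nrow(dt$tracks))
  for (k in seq_len(nrow(dt$tracks))) {
    tid <- dt$tracks$track_id[k]
    t1 <- by_track[[tid]]
    area <- buffer_track(t1, radius_km = radius_km, res_km = res_km)
    rr <- area$rows[area$rows <= nrow(tri_surface)]
    cc <- area$cols[area$cols <= ncol(tri_surface)]
    m <- area$mask[seq_along(rr), seq_along(cc), drop = FALSE]
    pop <- mean(pop_surface[rr, cc, drop = FALSE][m])
    setd <- if (settlement_variant == "kernel") {
      mean(set_surface[rr, cc, drop = FALSE][m])
    } else {
      s <- landscape$settlements
      sum(dist_to_polyline(s$x_km, s$y_km, area$vx, area$vy) <= radius_km) /
        area$area_km2
    }
    tri <- mean(tri_surface[rr, cc, drop = FALSE][m])
    prim <- road_density(landscape$roads, area, "primary")
    seco <- road_density(landscape$roads, area, "secondary")
    ref <- refuge_metrics(label_patches(landscape$refuge, area), area)
    rows[[k]] <- data.frame(
      track_id = tid,
      individual_id = dt$tracks$individual_id[k],
      track_date = dt$tracks$track_date[k],
      area_km2 = area$area_km2,
      pop_density = pop, settlement_density = setd,
      primary_road = prim, secondary_road = seco, tri = tri,
      ref, stringsAsFactors = FALSE)
    if (verbose && k %% 200 == 0)
      message("extracted ", k, "/", nrow(dt$tracks), " tracks")
  }
  out <- do.call(rbind, rows)
  out$period <- assign_period(out$track_date)
  out$grid_cell_id <- grid_map$grid_cell_id[match(out$track_id, grid_map$track_id)]
  merge(out, attributes, by = "individual_id", sort = FALSE)
}
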