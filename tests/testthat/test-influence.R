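# Influence areas and covariate extraction: buffers, kernel density, road
# density, terrain ruggedness and refuge patch metrics.

test_that("track buffers have the expected geometry", {
  pt <- data.frame(x_km = 5, y_km = 5)
  a1 <- buffer_track(pt, radius_km = 1)
  expect_equal(a1$area_km2, pi, tolerance = 0.01)

  seg <- data.frame(x_km = c(4, 6), y_km = c(5, 5))
  a2 <- buffer_track(seg, radius_km = 1)
  expect_equal(a2$area_km2, 4 + pi, tolerance = 0.01)

  # buffer contains every fix
  tr <- data.frame(x_km = c(3, 4.2, 5.5), y_km = c(3, 3.8, 3.1))
  a3 <- buffer_track(tr)
  expect_true(all(dist_to_polyline(tr$x_km, tr$y_km, a3$vx, a3$vy) <= a3$radius_km))
})

test_that("kernel density integrates to total weight and is linear", {
  s <- data.frame(x_km = 5, y_km = 5, population = 120)
  k <- settlement_kernel_density(s, bandwidth_km = 1, extent_km = c(10, 10),
                                 res_km = 0.02)
  expect_equal(sum(k) * 0.02^2, 120, tolerance = 0.005)
  # compact support
  xc <- (seq_len(ncol(k)) - 0.5) * 0.02
  far <- which(abs(xc - 5) > 1.05)
  expect_true(all(k[, far] == 0))
  # linearity in weights
  k2 <- settlement_kernel_density(s, weights = 240, bandwidth_km = 1,
                                  extent_km = c(10, 10), res_km = 0.02)
  expect_equal(k2, 2 * k, tolerance = 1e-12)
  # no settlements -> all-zero surface
  k0 <- settlement_kernel_density(s[0, ], bandwidth_km = 1,
                                  extent_km = c(4, 4), res_km = 0.05)
  expect_true(all(k0 == 0))
})

test_that("road density clips exactly against the buffer", {
  area <- buffer_track(data.frame(x_km = 5, y_km = 5), radius_km = 1)
  roads <- data.frame(road_id = 1, class = "primary",
                      x0 = 0, y0 = 5, x1 = 10, y1 = 5)
  # chord through the disk centre: 2 km clipped length over pi km2
  expect_equal(road_density(roads, area, "primary"), 2 / pi, tolerance = 0.005)
  expect_equal(road_density(roads, area, "secondary"), 0)
  expect_error(road_density(roads, area, "cart_track"), "unknown road class")

  # splitting a polyline into touching segments leaves density unchanged
  halves <- data.frame(road_id = 1:2, class = "primary",
                       x0 = c(0, 5), y0 = 5, x1 = c(5, 10), y1 = 5)
  expect_equal(road_density(halves, area, "primary"),
               road_density(roads, area, "primary"), tolerance = 1e-9)
})

test_that("terrain ruggedness matches hand values and the oracle", {
  expect_true(all(terrain_ruggedness(matrix(7, 5, 5)) == 0))

  s <- 3.2
  plane <- matrix(rep(s * (1:6), each = 6), 6, 6)  # constant slope along cols
  tri <- terrain_ruggedness(plane)
  # interior cell: six neighbours differ by s -> sqrt(6 s^2)
  expect_equal(tri[3, 3], s * sqrt(6), tolerance = 1e-12)
  expect_true(all(tri >= 0))

  set.seed(9)
  z <- matrix(rnorm(100), 10, 10)
  expect_equal(terrain_ruggedness(z), oracle_tri(z), tolerance = 1e-12)
})

test_that("patch labelling follows the 8-connectivity rule", {
  m <- matrix(0L, 5, 5)
  m[2, 2] <- 1L; m[3, 3] <- 1L  # diagonal touch
  expect_equal(nrow(label_patches(m)), 1L)
  expect_equal(nrow(label_patches(m, connectivity = 4)), 2L)

  solid <- matrix(0L, 5, 5); solid[2:4, 2:4] <- 1L
  p <- label_patches(solid)
  expect_equal(p$cell_count, 9L)
  expect_equal(p$perimeter_edges, 12L)

  expect_equal(nrow(label_patches(matrix(0L, 4, 4))), 0L)
})

test_that("refuge metrics match closed-form cases", {
  area <- whole_raster_area(20, 20)
  # square patches of several sizes have FDI exactly 1
  for (s in c(2, 5, 9)) {
    m <- matrix(0L, 20, 20); m[1:s, 1:s] <- 1L
    rm1 <- refuge_metrics(label_patches(m), area)
    expect_equal(rm1$mean_fdi, 1, tolerance = 1e-12)
    expect_equal(rm1$refuge_cover_pct, 100 * s^2 / 400, tolerance = 1e-12)
  }
  # fully covered buffer: one patch, 100% cover
  full <- matrix(1L, 20, 20)
  rmf <- refuge_metrics(label_patches(full), area)
  expect_equal(rmf$refuge_cover_pct, 100)
  expect_equal(rmf$patch_density * area$area_km2, 1)
  # a single isolated cell has cohesion 0
  one <- matrix(0L, 20, 20); one[7, 7] <- 1L
  expect_equal(refuge_metrics(label_patches(one), area)$mean_cohesion, 0)
  # no patches: cover and density 0, shape metrics undefined
  rm0 <- refuge_metrics(label_patches(matrix(0L, 20, 20)), area)
  expect_equal(rm0$refuge_cover_pct, 0)
  expect_equal(rm0$patch_density, 0)
  expect_true(is.na(rm0$mean_fdi))
})

test_that("refuge cover is monotone when refuge cells are added", {
  set.seed(31)
  area <- whole_raster_area(15, 15)
  m <- matrix(rbinom(225, 1, 0.3), 15, 15)
  cov1 <- refuge_metrics(label_patches(m), area)$refuge_cover_pct
  m2 <- m
  m2[sample(which(m == 0), 20)] <- 1L
  cov2 <- refuge_metrics(label_patches(m2), area)$refuge_cover_pct
  expect_gt(cov2, cov1)
})

test_that("patch metrics agree with brute-force pixel/edge enumeration", {
  set.seed(17)
  area <- whole_raster_area(20, 20)
  for (rep in 1:30) {
    m <- matrix(rbinom(400, 1, runif(1, 0.2, 0.7)), 20, 20)
    p <- label_patches(m)
    o <- oracle_patches(m)
    expect_equal(nrow(p), nrow(o))
    expect_equal(sort(p$cell_count), sort(o$cell_count))
    # match patches by sorting on (count, perimeter)
    key <- function(d) d[order(d$cell_count, d$perimeter_edges),
                         c("cell_count", "perimeter_edges")]
    expect_equal(key(p), key(o), ignore_attr = TRUE)

    rm1 <- refuge_metrics(p, area)
    expect_equal(rm1$refuge_cover_pct, 100 * sum(o$cell_count) / 400,
                 tolerance = 1e-9)
    expect_equal(rm1$patch_density, nrow(o) / area$area_km2, tolerance = 1e-9)
    ofdi <- ifelse(o$cell_count == 1, 1,
                   2 * log(0.25 * o$perimeter_edges) / log(o$cell_count))
    expect_equal(rm1$mean_fdi, mean(pmin(2, pmax(1, ofdi))), tolerance = 1e-9)
    ocoh <- (1 - sum(o$perimeter_edges) / sum(o$perimeter_edges * sqrt(o$cell_count))) /
      (1 - 1 / sqrt(400))
    expect_equal(rm1$mean_cohesion, ocoh, tolerance = 1e-9)
  }
})

test_that("extracted covariates are complete and labelled per track", {
  ls1 <- generate_landscape(landscape_config(extent_km = c(6, 6), seed = 13))
  tr <- simulate_tracks(ls1, sim_config(n_individuals = 2, days_per_individual = 8,
                                        missingness_rate = 0, seed = 5),
                        default_truth())
  dtf <- filter_complete(segment_days(tr$fixes))
  cov <- extract_covariates(dtf, ls1, tr$attributes)
  expect_equal(nrow(cov), nrow(dtf$tracks))
  expect_true(all(cov$refuge_cover_pct >= 0 & cov$refuge_cover_pct <= 100))
  expect_true(all(cov$primary_road >= 0 & cov$secondary_road >= 0))
  expect_true(all(cov$mean_fdi >= 1 & cov$mean_fdi <= 2, na.rm = TRUE))
  expect_true(all(cov$period %in% c("mating", "breeding", "nonreproductive")))
  expect_true(all(grepl("^\\d+_\\d+$", cov$grid_cell_id)))
  expect_true(all(cov$sex %in% c("F", "M")))
})
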