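# Independent brute-force oracles. These deliberately use naive loops and a
# different algorithmic route than the package implementations.

# Build a fix table for one individual from coordinate vectors, at 2-h slots
# starting 16:00 on `date`.
make_track_fixes <- function(x, y, id = "w1", date = as.Date("2010-06-01")) {
  n <- length(x)
  t0 <- as.POSIXct(paste(date, "16:00:00"), tz = "UTC")
  data.frame(individual_id = id,
             timestamp = t0 + (seq_len(n) - 1) * 7200,
             x_km = x, y_km = y)
}

oracle_daily_distance <- function(x, y) {
  s <- 0
  for (i in 2:length(x)) s <- s + sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2)
  s
}

oracle_net_displacement <- function(x, y) {
  n <- length(x)
  sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2)
}

# Flood-fill patch labelling by repeated scanning (no graph library).
oracle_label <- function(m, connectivity = 8) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nextlab <- 0L
  offs <- if (connectivity == 8) {
    list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  } else list(c(-1,0), c(1,0), c(0,-1), c(0,1))
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (m[r, c] == 1 && lab[r, c] == 0L) {
      nextlab <- nextlab + 1L
      queue <- list(c(r, c))
      lab[r, c] <- nextlab
      while (length(queue)) {
        cur <- queue[[1]]; queue <- queue[-1]
        for (o in offs) {
          rr <- cur[1] + o[1]; cc <- cur[2] + o[2]
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
              m[rr, cc] == 1 && lab[rr, cc] == 0L) {
            lab[rr, cc] <- nextlab
            queue[[length(queue) + 1L]] <- c(rr, cc)
          }
        }
      }
    }
  }
  lab
}

# Per-patch cell count and perimeter by explicit edge enumeration.
oracle_patches <- function(m, connectivity = 8) {
  lab <- oracle_label(m, connectivity)
  np <- max(lab)
  if (np == 0)
    return(data.frame(patch_id = integer(), cell_count = integer(),
                      perimeter_edges = integer()))
  nr <- nrow(m); nc <- ncol(m)
  counts <- integer(np); perim <- integer(np)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    p <- lab[r, c]
    if (p == 0) next
    counts[p] <- counts[p] + 1L
    for (o in list(c(-1,0), c(1,0), c(0,-1), c(0,1))) {
      rr <- r + o[1]; cc <- c + o[2]
      outside <- rr < 1 || rr > nr || cc < 1 || cc > nc
      if (outside || lab[rr, cc] != p) perim[p] <- perim[p] + 1L
    }
  }
  data.frame(patch_id = seq_len(np), cell_count = counts,
             perimeter_edges = perim)
}

oracle_tri <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    s <- 0
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc)
        s <- s + (z[r, c] - z[rr, cc])^2
    }
    out[r, c] <- sqrt(s)
  }
  out
}

# Lag-k autocorrelation by explicit pair enumeration (O(n^2)).
oracle_acf <- function(e, id, day, k) {
  m <- mean(e)
  denom <- mean((e - m)^2)
  num <- 0; np <- 0L
  for (i in seq_along(e)) for (j in seq_along(e)) {
    if (id[i] == id[j] && day[j] - day[i] == k) {
      num <- num + (e[i] - m) * (e[j] - m)
      np <- np + 1L
    }
  }
  (num / np) / denom
}

# An influence_area covering a whole raster, for raster-only metric tests.
whole_raster_area <- function(nr, nc, cell_km = 0.01) {
  structure(list(vx = nc * cell_km / 2, vy = nr * cell_km / 2,
                 radius_km = Inf, res_km = cell_km,
                 rows = seq_len(nr), cols = seq_len(nc),
                 mask = matrix(TRUE, nr, nc),
                 area_km2 = nr * nc * cell_km^2),
            class = "influence_area")
}
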