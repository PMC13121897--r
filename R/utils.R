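# Internal numerical helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the previous
#' global RNG state so seeded package internals do not perturb user code.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Circular (periodic) convolution of matrix `m` with kernel `k` via FFT.
# `k` must have the same dimensions as `m` and be centred at element [1,1].
fft_convolve <- function(m, k) {
  Re(fft(fft(m) * fft(k), inverse = TRUE)) / length(m)
}

# Build a centred-at-origin kernel matrix of the same size as (nr, nc) from a
# radial profile function f(d_cells) evaluated on the torus distance.
radial_kernel <- function(nr, nc, f) {
  dr <- pmin(0:(nr - 1), nr - (0:(nr - 1)))
  dc <- pmin(0:(nc - 1), nc - (0:(nc - 1)))
  d <- sqrt(outer(dr^2, dc^2, `+`))
  f(d)
}

# Gaussian smoothing of a matrix with SD `sigma` in cell units (periodic edges).
smooth_field <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- radial_kernel(nrow(m), ncol(m), function(d) exp(-d^2 / (2 * sigma^2)))
  fft_convolve(m, k / sum(k))
}

# Mean of `m` over a disk of `radius` cells around every cell (periodic edges).
disk_mean <- function(m, radius) {
  k <- radial_kernel(nrow(m), ncol(m), function(d) as.numeric(d <= radius))
  fft_convolve(m, k / sum(k))
}

# Quantile convention used throughout the package: linear interpolation
# (type 7), the R default, documented for Q1/Q3/IQR reproducibility.
quantile_lin <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_predmove <- function(...) stop(..., call. = FALSE)

# Distance from points (px, py) to a polyline given by vertex vectors (vx, vy).
# Vectorised over points; loops over segments (tracks have <= 11 segments).
dist_to_polyline <- function(px, py, vx, vy) {
  n <- length(vx)
  if (n == 1L) return(sqrt((px - vx)^2 + (py - vy)^2))
  d2 <- rep(Inf, length(px))
  for (i in seq_len(n - 1L)) {
    ax <- vx[i]; ay <- vy[i]; bx <- vx[i + 1L]; by <- vy[i + 1L]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      dd <- (px - ax)^2 + (py - ay)^2
    } else {
      t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
      dd <- (px - ax - t * dx)^2 + (py - ay - t * dy)^2
    }
    d2 <- pmin(d2, dd)
  }
  sqrt(d2)
}
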