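# Internal helpers: units, seeded evaluation, small filters.

# 1 uL = 1e9 um^3; flow rates are user-facing in uL/min, internal in um^3/s.
ul_min_to_um3_s <- function(q) q * 1e9 / 60

# Evaluate expr with a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# 1D Gaussian kernel, truncated at +-truncate*sigma, normalized.
gauss_kernel1d <- function(sigma, truncate = 4) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(truncate * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur of a matrix with reflective edge handling.
blur2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gauss_kernel1d(sigma)
  m <- apply_conv1(m, k, along = 1L)
  apply_conv1(m, k, along = 2L)
}

# Convolve each column (along=1) or row (along=2) of a matrix with kernel k,
# reflective padding.
apply_conv1 <- function(m, k, along = 1L) {
  if (length(k) == 1L) return(m)
  if (along == 2L) return(t(apply_conv1(t(m), k, along = 1L)))
  r <- (length(k) - 1L) / 2L
  n <- nrow(m)
  idx <- c(pmin(n, pmax(1L, (r + 1L):2L)), 1L:n, pmax(1L, pmin(n, (n - 1L):(n - r))))
  mp <- m[idx, , drop = FALSE]
  # circular FFT convolution on the padded rows; the wrap only reaches the
  # pad (kernel half-width == pad width), which is cropped afterwards.
  # Rows are zero-extended to a 2-3-5-smooth length for FFT speed.
  np <- stats::nextn(n + 2L * r, c(2L, 3L, 5L))
  if (np > n + 2L * r)
    mp <- rbind(mp, matrix(0, np - n - 2L * r, ncol(mp)))
  kv <- numeric(np)
  kv[1:(r + 1L)] <- k[(r + 1L):(2L * r + 1L)]
  kv[(np - r + 1L):np] <- k[1:r]
  out <- Re(stats::mvfft(stats::mvfft(mp) * as.vector(stats::fft(kv)),
                         inverse = TRUE)) / np
  out[(r + 1L):(r + n), , drop = FALSE]
}

conv1d <- function(x, k) {
  r <- (length(k) - 1L) / 2L
  n <- length(x)
  xp <- c(x[pmin(n, pmax(1L, (r + 1L):2L))], x, x[pmax(1L, pmin(n, (n - 1L):(n - r)))])
  as.numeric(stats::filter(xp, k, sides = 2))[(r + 1L):(r + n)]
}

# Bilinear interpolation of matrix m at fractional (i, j) positions (1-based).
bilinear <- function(m, i, j) {
  i <- pmin(pmax(i, 1), nrow(m)); j <- pmin(pmax(j, 1), ncol(m))
  i0 <- pmin(floor(i), nrow(m) - 1L); j0 <- pmin(floor(j), ncol(m) - 1L)
  di <- i - i0; dj <- j - j0
  m[cbind(i0, j0)] * (1 - di) * (1 - dj) + m[cbind(i0 + 1L, j0)] * di * (1 - dj) +
    m[cbind(i0, j0 + 1L)] * (1 - di) * dj + m[cbind(i0 + 1L, j0 + 1L)] * di * dj
}

# Sub-pixel position of an extremum from a 3-point quadratic fit; returns the
# offset in [-0.5, 0.5] relative to the central sample.
quad_subpixel <- function(ym1, y0, yp1) {
  if (!all(is.finite(c(ym1, y0, yp1)))) return(0)
  den <- ym1 - 2 * y0 + yp1
  if (abs(den) < .Machine$double.eps) return(0)
  max(-0.5, min(0.5, 0.5 * (ym1 - yp1) / den))
}

# Gaussian blur of every frame of a (nx, ny, nt) array, as two vectorized
# separable passes (reflective edges, truncation 3 sigma). Processed in
# frame blocks to bound the FFT working memory.
blur_frames <- function(frames, sigma, block_voxels = 6e6) {
  if (sigma <= 0) return(frames)
  k <- gauss_kernel1d(sigma, truncate = 3)
  d <- dim(frames)
  out <- frames
  step <- max(1L, floor(block_voxels / (d[1] * d[2])))
  for (f0 in seq(1L, d[3], by = step)) {
    f1 <- min(d[3], f0 + step - 1L)
    blk <- frames[, , f0:f1, drop = FALSE]
    db <- dim(blk)
    m <- apply_conv1(matrix(blk, db[1]), k, along = 1L)   # conv along x
    a <- aperm(array(m, db), c(2L, 1L, 3L))
    m <- apply_conv1(matrix(a, db[2]), k, along = 1L)     # conv along y
    out[, , f0:f1] <- aperm(array(m, c(db[2], db[1], db[3])), c(2L, 1L, 3L))
  }
  out
}
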