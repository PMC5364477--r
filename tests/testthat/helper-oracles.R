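# Independent oracles used by the tests. These deliberately avoid the code
# paths they check.

# Finite-difference solution of the duct Poisson problem (-lap u = 1,
# u = 0 on the boundary) on an n x n grid over a square of side `side`.
# Returns the velocity field scaled to unit flow rate plus V_max/V_avg.
fd_duct_solve <- function(side = 1, n = 201L) {
  h <- side / (n + 1)
  idx <- function(i, j) (j - 1L) * n + i
  N <- n * n
  ii <- jj <- integer(0); xx <- numeric(0)
  ivec <- rep(seq_len(n), times = n)
  jvec <- rep(seq_len(n), each = n)
  add <- function(a, b, v) { ii <<- c(ii, a); jj <<- c(jj, b); xx <<- c(xx, v) }
  add(idx(ivec, jvec), idx(ivec, jvec), rep(4, N))
  w <- ivec > 1L; add(idx(ivec[w], jvec[w]), idx(ivec[w] - 1L, jvec[w]), rep(-1, sum(w)))
  w <- ivec < n;  add(idx(ivec[w], jvec[w]), idx(ivec[w] + 1L, jvec[w]), rep(-1, sum(w)))
  w <- jvec > 1L; add(idx(ivec[w], jvec[w]), idx(ivec[w], jvec[w] - 1L), rep(-1, sum(w)))
  w <- jvec < n;  add(idx(ivec[w], jvec[w]), idx(ivec[w], jvec[w] + 1L), rep(-1, sum(w)))
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N))
  u <- as.numeric(Matrix::solve(A, rep(h^2, N)))
  um <- matrix(u, n, n)
  # interior-node quadrature of the flow (boundary values are zero)
  q <- sum(um) * h^2
  list(u = um, h = h, vmax_vavg = max(um) * side^2 / q,
       coords = seq_len(n) * h - side / 2)
}

# Brute-force FWHM of a point-sampled top-hat of width w (um) at pixel size
# px, for a given sampling phase in [0, 1): linear interpolation between the
# 0/1 samples at the half level, same convention as fwhm().
tophat_fwhm_oracle <- function(w, px, phase) {
  x <- (seq(-20, 20) + phase) * px
  y <- as.numeric(abs(x) <= w / 2)
  ipk <- which.max(y)
  half <- 0.5
  il <- max(which(y[seq_len(ipk - 1)] < half))
  jr <- ipk + min(which(y[(ipk + 1):length(y)] < half))
  xl <- x[il] + (half - y[il]) / (y[il + 1] - y[il]) * px
  xr <- x[jr - 1] + (half - y[jr - 1]) / (y[jr] - y[jr - 1]) * px
  xr - xl
}

# Small ESL stack simulations shared across test files.
flat_shell_sim <- function(thickness = 0.67, sd = 0.15, noise = NULL,
                           psf = NULL, side = 15, seed = 3L) {
  make_esl_stack(surface_spec(base_offset = 0.9, hump_height = 0, seed = seed + 1L),
                 shell_spec(thickness, sd, seed = seed),
                 channel_side = side, psf = psf, noise = noise, wall = "left")
}

default_psf <- function() generate_psf(1.3, 0.52, 1.518, c(0.225, 0.225, 0.5))

# A small-scale time-lapse experiment (shorter frame and duration than the
# full acquisition) for module-level tracking tests.
small_timelapse <- function(mode = "uniform", seed = 11L, duration = 1.5,
                            tracer_count = 250L, depletion = 3.8) {
  fl <- flow_spec(lateral_mode = mode, tracer_count = tracer_count,
                  depletion_width = depletion, seed = seed)
  duct <- duct_flow_model(fl$channel_width, fl$channel_height,
                          fl$flow_rate_per_channel)
  sim <- make_rbc_timelapse(fl, duct, duration = duration,
                            frame_px = c(256L, 100L))
  c(sim, list(flow = fl, duct = duct))
}
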