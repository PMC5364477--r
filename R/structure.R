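#' Temporal projections of a time-lapse stack
#'
#' Per-pixel mean and (population) standard deviation along the time axis.
#' The mean image retains only static structures (the stained wall layer);
#' the standard-deviation image retains only intensity fluctuations, i.e.
#' the accumulated paths of the flowing cells.
#'
#' @param stack a [timelapse_stack()] with at least 50 frames.
#' @return An object of class `t_projections` with `mean_image`, `std_image`,
#'   `n_frames`, `pixel_size`.
#' @export
t_project <- function(stack) {
  stopifnot(inherits(stack, "timelapse_stack"))
  nf <- dim(stack$frames)[3]
  if (nf < 50) stop("need at least 50 frames for temporal projections")
  m <- rowMeans(stack$frames, dims = 2)
  m2 <- rowMeans(stack$frames^2, dims = 2)
  structure(list(mean_image = m, std_image = sqrt(pmax(m2 - m^2, 0)),
                 n_frames = nf, pixel_size = stack$pixel_size),
            class = "t_projections")
}

# Centre position (um, relative to first column) of the peak nearest `side`
# of a cross-channel profile, as the midpoint of its half-level crossings.
peak_center_halfheight <- function(y, coords, half) {
  i <- which.max(y)
  il <- i; while (il > 1 && y[il] > half) il <- il - 1L
  ir <- i; while (ir < length(y) && y[ir] > half) ir <- ir + 1L
  if (y[il] > half || y[ir] > half) return(NA_real_)
  xl <- coords[il] + (half - y[il]) / (y[il + 1L] - y[il]) * (coords[il + 1L] - coords[il])
  xr <- coords[ir - 1L] + (half - y[ir - 1L]) / (y[ir] - y[ir - 1L]) * (coords[ir] - coords[ir - 1L])
  (xl + xr) / 2
}

#' Cell-free-layer thickness from temporal projections
#'
#' At each of `n_positions` streamwise locations, cross-channel profiles are
#' taken after streamwise averaging over a window (suppressing the ~10 um
#' streamwise modulation left by frame-to-frame cell travel). The channel
#' width `w_ch` is the distance between the two wall-band peak centres of the
#' mean-projection profile (each centre taken at half height). The RBC
#' column width `w_RBC` is the mid-height width of the central bump of the
#' temporal-variance profile (variance rather than standard deviation, since
#' the variance is linear in the local cell occupancy) after the profile is
#' deconvolved by the lateral cell kernel: a cell of finite size smears the
#' column edge by its own radius, and near-wall cells are over-weighted by
#' their longer residence time, which together shift the raw mid-height
#' crossing outward; deconvolving restores a sharp edge at the cell-centre
#' column boundary. The depleted-layer thickness is
#' `h_dep = (w_ch - w_RBC) / 2`.
#'
#' @param proj a [t_project()] result.
#' @param n_positions number of streamwise measurement positions.
#' @param window_um streamwise averaging window, um.
#' @param spot_diameter apparent cell image diameter, um; the variance
#'   profile is deconvolved with a Gaussian of sigma `spot_diameter / 4`
#'   (the variance kernel of a Gaussian-profile cell). 0 disables the
#'   deconvolution.
#' @param deconv_iters Richardson-Lucy iterations for the 1D deconvolution.
#' @return A data frame with one row per position (`x_um`, `w_ch`, `w_rbc`,
#'   `h_dep`) plus attributes `h_dep_mean` and `h_dep_sd`.
#' @export
cfl_thickness <- function(proj, n_positions = 12L, window_um = 10,
                          spot_diameter = 7.1, deconv_iters = 60L) {
  stopifnot(inherits(proj, "t_projections"), n_positions >= 1)
  px <- proj$pixel_size
  nx <- nrow(proj$mean_image); ny <- ncol(proj$mean_image)
  yc <- (seq_len(ny) - 1) * px
  half_w <- max(1L, round(window_um / px / 2))
  xs <- round(seq(1 + half_w, nx - half_w, length.out = n_positions))
  var_img <- proj$std_image^2
  res <- lapply(xs, function(ix) {
    rows <- max(1L, ix - half_w):min(nx, ix + half_w)
    pm <- conv1d(colMeans(proj$mean_image[rows, , drop = FALSE]), gauss_kernel1d(1))
    pv <- conv1d(colMeans(var_img[rows, , drop = FALSE]), gauss_kernel1d(1))
    mid <- floor(ny / 2)
    bgm <- profile_background(pm)
    left <- pm[seq_len(mid)]; right <- pm[(mid + 1L):ny]
    if (max(left) <= bgm || max(right) <= bgm) stop("missing wall peak")
    cl <- peak_center_halfheight(left, yc[seq_len(mid)],
                                 bgm + (max(left) - bgm) / 2)
    cr <- peak_center_halfheight(right, yc[(mid + 1L):ny],
                                 bgm + (max(right) - bgm) / 2)
    if (!is.finite(cl) || !is.finite(cr)) stop("missing wall peak")
    w_ch <- cr - cl
    # central bump of the variance profile, restricted to between the walls
    inb <- yc > cl & yc < cr
    if (spot_diameter > 0) {
      # undo the lateral smearing by the finite cell size (sigma of the
      # variance kernel, plus the profile smoothing applied above)
      sig_px <- sqrt((spot_diameter / 4 / px)^2 + 1)
      pv <- rl_deconv1d(pv, sig_px, deconv_iters)
    }
    pin <- pv; pin[!inb] <- 0
    # background: the depleted zones next to the walls (low quantile of the
    # in-wall profile); bump level: median of the supra-threshold column
    # (robust to clustering bumps and to edge-weighted bathtub shapes)
    bgv <- stats::quantile(pv[inb], 0.1, names = FALSE)
    mx <- max(pin)
    if (mx <= bgv) stop("central bump not resolved")
    core <- inb & pin > bgv + 0.25 * (mx - bgv)
    lev <- stats::median(pv[core])
    halfv <- bgv + (lev - bgv) / 2
    # outermost half-level crossings of the column, scanning inward from
    # the walls (the interior may dip below the half level)
    idx <- which(inb & pin >= halfv)
    if (length(idx) == 0L) stop("central bump not resolved")
    il <- min(idx); ir <- max(idx)
    xl <- if (il > 1L && pin[il - 1L] < halfv)
      yc[il - 1L] + (halfv - pin[il - 1L]) / (pin[il] - pin[il - 1L]) * px
    else yc[il]
    xr <- if (ir < ny && pin[ir + 1L] < halfv)
      yc[ir] + (pin[ir] - halfv) / (pin[ir] - pin[ir + 1L]) * px
    else yc[ir]
    w_rbc <- xr - xl
    data.frame(x_um = (ix - 0.5) * px, w_ch = w_ch, w_rbc = w_rbc,
               h_dep = (w_ch - w_rbc) / 2)
  })
  out <- do.call(rbind, res)
  attr(out, "h_dep_mean") <- mean(out$h_dep)
  attr(out, "h_dep_sd") <- stats::sd(out$h_dep)
  out
}

# 1D Richardson-Lucy deconvolution with a Gaussian kernel (reflective
# edges); used to sharpen cross-channel variance profiles.
rl_deconv1d <- function(y, sigma_px, iters = 60L) {
  k <- gauss_kernel1d(sigma_px, truncate = 3)
  obs <- pmax(y, 0)
  eps <- 1e-12 * max(obs, 1e-300)
  est <- pmax(obs, eps)
  for (i in seq_len(iters)) {
    blur <- pmax(conv1d(est, k), eps)
    est <- est * conv1d(obs / blur, k)
  }
  est
}

#' Normalized cross-stream distribution of cell trajectories
#'
#' The channel width is split into 30 adjacent 1-um bins centred on the
#' axis; trajectory counts per bin are converted to a linear number density
#' (`N_i / dy`) and normalized by the average density (`N_tot / mean_width`).
#'
#' @param tracks an `rbc_tracks` object or a data frame with `mean_y` (um,
#'   origin on the channel axis).
#' @param mean_width the mean inner channel width used for normalization, um.
#' @param n_bins number of bins (default 30).
#' @param bin_width bin width, um (default 1).
#' @return An object of class `lateral_distribution`: `bin_centers`,
#'   `counts`, `density` (normalized), `n_tracks`, `n_excluded`, and the
#'   detected `peaks` (positions, separation, max/mean contrast).
#' @export
lateral_distribution <- function(tracks, mean_width, n_bins = 30L,
                                 bin_width = 1) {
  pts <- if (inherits(tracks, "rbc_tracks")) tracks$tracks else tracks
  stopifnot("mean_y" %in% names(pts), mean_width > 0)
  y <- pts$mean_y
  half_span <- n_bins * bin_width / 2
  breaks <- seq(-half_span, half_span, by = bin_width)
  inside <- y >= -half_span & y <= half_span
  n_excluded <- sum(!inside)
  y <- y[inside]
  if (length(y) < 2) stop("too few trajectories inside the binned range")
  counts <- graphics::hist(y, breaks = breaks, plot = FALSE)$counts
  density <- (counts / bin_width) / (length(y) / mean_width)
  centers <- breaks[-1] - bin_width / 2
  occupied <- density > 0
  # peak detection on a lightly smoothed density (counting noise suppresses
  # spurious single-bin maxima); the two strongest well-separated maxima
  dens_s <- conv1d(density, c(0.25, 0.5, 0.25))
  pk <- pracma::findpeaks(dens_s, minpeakheight = 0.4 * max(dens_s),
                          minpeakdistance = 4)
  peaks <- NULL
  if (!is.null(pk) && nrow(pk) >= 1) {
    pk <- pk[order(pk[, 1], decreasing = TRUE), , drop = FALSE]
    pos <- centers[pk[seq_len(min(2L, nrow(pk))), 2]]
    peaks <- list(positions = sort(pos),
                  separation = if (length(pos) >= 2) max(pos) - min(pos) else NA_real_,
                  contrast = max(density) / mean(density[occupied]))
  }
  structure(list(bin_centers = centers, counts = counts, density = density,
                 n_tracks = length(y), n_excluded = n_excluded,
                 mean_width = mean_width, peaks = peaks),
            class = "lateral_distribution")
}

#' @export
print.lateral_distribution <- function(x, ...) {
  cat(sprintf("<lateral_distribution> %d tracks in %d bins", x$n_tracks,
              length(x$bin_centers)))
  if (!is.null(x$peaks) && length(x$peaks$positions) >= 2)
    cat(sprintf("; peaks at %s um (sep %.1f um, contrast %.2f)",
                paste(sprintf("%.1f", x$peaks$positions), collapse = ", "),
                x$peaks$separation, x$peaks$contrast))
  cat("\n"); invisible(x)
}

#' In-channel hematocrit from cell counts
#'
#' The volume fraction of red blood cells in the imaged channel:
#' `Ht(%) = N v / (Q_channel dT) x 100`, with `N` the number of cells counted
#' over the interval `dT`, `v` the mean cell volume and `Q_channel` the
#' per-channel flow rate (`Q_total / n_parallel`).
#'
#' @param n_cells number of cells counted during `dT`.
#' @param cell_volume mean cell volume, fL (default 90).
#' @param q_total total imposed flow rate, uL/min.
#' @param n_parallel number of parallel channels sharing the flow.
#' @param dT counting interval, s.
#' @return An object of class `hematocrit_estimate` with field `ht` (percent).
#' @export
hematocrit <- function(n_cells, cell_volume = 90, q_total = 1,
                       n_parallel = 16L, dT = 3) {
  stopifnot(n_cells >= 0, cell_volume > 0, q_total > 0, n_parallel >= 1,
            dT > 0)
  q_channel <- q_total / n_parallel               # uL/min
  q_ul_s <- q_channel / 60                        # uL/s
  v_ul <- cell_volume * 1e-9                      # fL -> uL
  ht <- n_cells * v_ul / (q_ul_s * dT) * 100
  structure(list(N = n_cells, v = cell_volume, Q_channel = q_channel,
                 dT = dT, ht = ht),
            class = "hematocrit_estimate")
}

#' @export
print.hematocrit_estimate <- function(x, ...) {
  cat(sprintf("<hematocrit_estimate> Ht = %.3g%% (N = %d, v = %g fL, Q = %g uL/min per channel, dT = %g s)\n",
              x$ht, x$N, x$v, x$Q_channel, x$dT))
  invisible(x)
}

#' Cumulated-area bookkeeping of the travelling cells
#'
#' Total image area covered by the flowing cells over a sequence
#' (`n_cells x cell_area x frames_visible`) and its ratio to the imaged
#' channel section; a large ratio justifies interpreting structure in the
#' temporal projections as genuine flow structure rather than sampling
#' noise.
#'
#' @param n_cells number of cells travelling through the imaged plane.
#' @param cell_area plan-view area of one cell, um^2 (default 40).
#' @param frames_visible number of frames each cell stays in view.
#' @param section_area area of the imaged channel section, um^2.
#' @return A list with `area` (um^2) and `ratio`.
#' @export
cumulated_area_check <- function(n_cells, cell_area = 40, frames_visible,
                                 section_area = 7000) {
  stopifnot(n_cells >= 0, cell_area > 0, frames_visible >= 0, section_area > 0)
  area <- n_cells * cell_area * frames_visible
  list(area = area, ratio = area / section_area)
}
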