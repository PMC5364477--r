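#' Intensity profile across the fluorescent surface layer
#'
#' @param positions strictly increasing sample positions along the profile, um.
#' @param intensities intensities at those positions (a.u.).
#' @param origin optional (x, y, z) voxel position of the profile centre.
#' @param direction optional unit 2-vector of the profile direction in the
#'   XY plane.
#' @return An object of class `intensity_profile`.
#' @export
intensity_profile <- function(positions, intensities, origin = NULL,
                              direction = NULL) {
  stopifnot(length(positions) == length(intensities), length(positions) >= 5,
            all(diff(positions) > 0))
  structure(list(positions = as.numeric(positions),
                 intensities = as.numeric(intensities),
                 origin = origin, direction = direction),
            class = "intensity_profile")
}

# Background level convention used throughout: median of the outer 20% of
# samples (both profile ends pooled).
profile_background <- function(y) {
  n <- length(y)
  k <- max(1L, floor(0.1 * n))
  stats::median(c(y[seq_len(k)], y[(n - k + 1L):n]))
}

#' Full width at half maximum of an intensity profile
#'
#' The layer thickness estimator: width of the dominant peak at half of
#' (peak - background), with sub-sample precision by linear interpolation
#' between the bracketing samples. Background is the median of the outer 20%
#' of samples. Invariant under affine rescaling of the intensities.
#'
#' @param profile an [intensity_profile()].
#' @return FWHM in um. Profiles whose peak is not bracketed by half-level
#'   crossings on both sides (e.g. monotone ramps, edge peaks) are rejected
#'   with an error of class `vesselchip_fwhm_reject`.
#' @export
fwhm <- function(profile) {
  stopifnot(inherits(profile, "intensity_profile"))
  x <- profile$positions; y <- profile$intensities
  bg <- profile_background(y)
  ipk <- which.max(y)
  half <- bg + (y[ipk] - bg) / 2
  reject <- function(msg) stop(errorCondition(
    msg, class = c("vesselchip_fwhm_reject", "error")))
  if (y[ipk] <= bg) reject("no peak above background")
  if (ipk == 1L || ipk == length(y)) reject("peak at profile end")
  il <- which(y[seq_len(ipk - 1L)] < half)
  ir <- which(y[(ipk + 1L):length(y)] < half)
  if (length(il) == 0L || length(ir) == 0L)
    reject("peak not bracketed by half-level crossings on both sides")
  i0 <- max(il)                   # last sample below half on the left
  j0 <- ipk + min(ir)             # first sample below half on the right
  xl <- x[i0] + (half - y[i0]) / (y[i0 + 1L] - y[i0]) * (x[i0 + 1L] - x[i0])
  xr <- x[j0 - 1L] + (half - y[j0 - 1L]) / (y[j0] - y[j0 - 1L]) * (x[j0] - x[j0 - 1L])
  xr - xl
}

#' Extract intensity profiles across the wall layer of a deconvolved stack
#'
#' Works on XY planes of a stack imaging a lateral channel wall: in each
#' plane the fluorescent layer appears as a bright, roughly y-parallel ridge.
#' The ridge is located per row as the intensity maximum along x, smoothed
#' along y, and profiles are drawn along the local ridge normal with bilinear
#' interpolation. Profile sites are sampled with a fixed seed, uniformly over
#' the available planes and ridge positions with a minimum spacing along the
#' ridge of `min_spacing`.
#'
#' @param stack a deconvolved [image_stack3d()] imaging a lateral wall.
#' @param n_profiles number of profiles requested.
#' @param seed integer seed for the site sampling.
#' @param half_length profile half-length, um (profiles span at least 3 um).
#' @param min_spacing minimum spacing between profile sites along the ridge, um.
#' @param noise_floor intensity below which no wall signal is deemed present,
#'   as a fraction of nothing-detected errors (absolute units).
#' @return A list of [intensity_profile()] objects of length `n_profiles`.
#' @export
extract_profiles <- function(stack, n_profiles = 140L, seed = 1L,
                             half_length = 1.6, min_spacing = 1,
                             noise_floor = 1e-6) {
  stopifnot(inherits(stack, "image_stack3d"), n_profiles >= 1)
  if (max(stack$data) <= noise_floor)
    stop("no wall signal detected: stack maximum below the noise floor")
  d <- dim(stack$data)
  dx <- stack$spacing[1]; dy <- stack$spacing[2]
  half_length <- max(half_length, 1.5)
  # candidate sites: (z plane, y row) with min spacing along y
  step <- max(1L, round(min_spacing / dy))
  rows <- seq(2L, d[2] - 1L, by = step)
  sites <- expand.grid(iy = rows, iz = seq_len(d[3]))
  if (nrow(sites) < n_profiles)
    stop(sprintf("insufficient wall extent: %d candidate sites for %d profiles",
                 nrow(sites), n_profiles))
  pick <- with_seed(seed, sites[sample.int(nrow(sites), n_profiles), ])
  smooth_k <- gauss_kernel1d(2)
  ns <- ceiling(half_length / dx)
  offs <- seq(-ns, ns) * dx
  out <- vector("list", n_profiles)
  ridge_cache <- list()
  for (p in seq_len(n_profiles)) {
    iz <- pick$iz[p]; iy <- pick$iy[p]
    key <- as.character(iz)
    if (is.null(ridge_cache[[key]])) {
      plane <- stack$data[, , iz]
      ridge <- apply(plane, 2, which.max)
      ridge_cache[[key]] <- list(plane = plane,
                                 ridge = conv1d(ridge, smooth_k))
    }
    rc <- ridge_cache[[key]]
    # local normal from the ridge slope dx/dy (in um)
    i1 <- max(1L, iy - 2L); i2 <- min(d[2], iy + 2L)
    slope <- (rc$ridge[i2] - rc$ridge[i1]) * dx / ((i2 - i1) * dy)
    nrm <- c(1, -slope) / sqrt(1 + slope^2)
    cx <- rc$ridge[iy]; cy <- iy
    ii <- cx + offs * nrm[1] / dx
    jj <- cy + offs * nrm[2] / dy
    vals <- bilinear(rc$plane, ii, jj)
    out[[p]] <- intensity_profile(offs - offs[1], vals,
                                  origin = c(cx, cy, iz), direction = nrm)
  }
  out
}

#' Aggregate FWHM thickness measurements
#'
#' Computes the summary statistics and histogram of a set of accepted
#' surface-layer thickness measurements, and flags the fraction of sites
#' where the layer reaches 1 um or more.
#'
#' @param fwhm_values numeric vector of accepted FWHM values, um (length >= 2).
#' @param histogram_bin histogram bin width, um.
#' @param channel_ids optional labels of the source channels.
#' @return An object of class `esl_measurement_set`: values, `mean`, `sd`,
#'   `n`, `frac_ge_1um`, and the histogram (`breaks`, `counts`).
#' @export
aggregate_fwhm <- function(fwhm_values, histogram_bin = 0.1,
                           channel_ids = NULL) {
  fwhm_values <- fwhm_values[is.finite(fwhm_values)]
  if (length(fwhm_values) < 2)
    stop("need at least 2 accepted measurements to aggregate")
  breaks <- seq(0, ceiling(max(fwhm_values) / histogram_bin) * histogram_bin,
                by = histogram_bin)
  h <- graphics::hist(fwhm_values, breaks = breaks, plot = FALSE)
  structure(list(fwhm_values = fwhm_values,
                 mean = mean(fwhm_values),
                 sd = stats::sd(fwhm_values),
                 n = length(fwhm_values),
                 frac_ge_1um = mean(fwhm_values >= 1),
                 breaks = h$breaks, counts = h$counts,
                 channel_ids = channel_ids),
            class = "esl_measurement_set")
}

#' @export
print.esl_measurement_set <- function(x, ...) {
  cat(sprintf("<esl_measurement_set> n = %d, thickness = %.3g +/- %.2g um (%.0f%% of sites >= 1 um)\n",
              x$n, x$mean, x$sd, 100 * x$frac_ge_1um))
  invisible(x)
}

#' Measure surface-layer thickness over many profiles
#'
#' Convenience wrapper: extracts profiles, applies the FWHM estimator,
#' flags rejected profiles, and aggregates the accepted values.
#'
#' @inheritParams extract_profiles
#' @param histogram_bin histogram bin width passed to [aggregate_fwhm()].
#' @return A list with `summary` (an `esl_measurement_set`) and `measurements`
#'   (a data frame with one row per profile: origin, direction, fwhm,
#'   accepted flag).
#' @export
measure_esl <- function(stack, n_profiles = 140L, seed = 1L,
                        half_length = 1.6, histogram_bin = 0.1) {
  profs <- extract_profiles(stack, n_profiles = n_profiles, seed = seed,
                            half_length = half_length)
  vals <- vapply(profs, function(p) {
    tryCatch(fwhm(p), vesselchip_fwhm_reject = function(e) NA_real_)
  }, numeric(1))
  meas <- data.frame(
    x = vapply(profs, function(p) p$origin[1], numeric(1)),
    y = vapply(profs, function(p) p$origin[2], numeric(1)),
    z = vapply(profs, function(p) p$origin[3], numeric(1)),
    dir_x = vapply(profs, function(p) p$direction[1], numeric(1)),
    dir_y = vapply(profs, function(p) p$direction[2], numeric(1)),
    fwhm = vals, accepted = is.finite(vals))
  list(summary = aggregate_fwhm(vals, histogram_bin = histogram_bin),
       measurements = meas)
}

#' Mean-intensity ratio between two stacks
#'
#' Helper for qualitative before/after comparisons (e.g. enzymatic layer
#' degradation): ratio of mean intensities above background.
#'
#' @param stack_a,stack_b two [image_stack3d()] objects.
#' @return `mean(a) / mean(b)`.
#' @export
mean_intensity_ratio <- function(stack_a, stack_b) {
  stopifnot(inherits(stack_a, "image_stack3d"), inherits(stack_b, "image_stack3d"))
  mean(stack_a$data) / mean(stack_b$data)
}
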