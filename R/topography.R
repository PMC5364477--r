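#' Height map of the endothelial apical membrane
#'
#' @param heights 2D matrix of heights above the wall plane, um,
#'   zero-referenced so that the lowest point is 0.
#' @param lateral_spacing numeric length-2 lateral grid spacing, um.
#' @param wall which wall the map was extracted from.
#' @param missing logical matrix flagging cells filled by interpolation.
#' @return An object of class `height_map`.
#' @export
height_map <- function(heights, lateral_spacing, wall = "bottom",
                       missing = NULL) {
  stopifnot(is.matrix(heights), length(lateral_spacing) == 2L,
            all(lateral_spacing > 0), all(heights >= 0))
  if (is.null(missing)) missing <- matrix(FALSE, nrow(heights), ncol(heights))
  structure(list(heights = heights, lateral_spacing = as.numeric(lateral_spacing),
                 wall = wall, missing = missing),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %d x %d cells (%s wall), range 0 - %.3g um, %.1f%% interpolated\n",
              nrow(x$heights), ncol(x$heights), x$wall, max(x$heights),
              100 * mean(x$missing)))
  invisible(x)
}

#' Extract the membrane height map from an XYZ stack
#'
#' Follows the edge-detect / threshold / skeletonize recipe: a Sobel-type
#' gradient magnitude is computed, thresholded with Otsu's method, and for
#' each lateral grid cell the innermost (lumen-facing) supra-threshold run
#' along the wall normal is reduced to its medial position, which defines the
#' local surface height. Heights are zero-referenced to the map minimum; gaps
#' are filled by nearest-neighbour interpolation and flagged.
#'
#' @param stack an [image_stack3d()] containing the stained wall layer.
#' @param wall `"bottom"`, `"top"`, `"left"` or `"right"`: which wall the
#'   surface lines. Determines the normal axis and the lumen direction.
#' @param max_missing maximum tolerated fraction of unresolved cells before
#'   the surface is declared unresolvable.
#' @return A [height_map()].
#' @export
extract_surface <- function(stack, wall = c("bottom", "top", "left", "right"),
                            max_missing = 0.2) {
  stopifnot(inherits(stack, "image_stack3d"))
  wall <- match.arg(wall)
  # permute so the wall normal is axis 3 with the lumen towards increasing index
  a <- stack$data; sp <- stack$spacing
  perm <- switch(wall,
                 bottom = c(1L, 2L, 3L), top = c(1L, 2L, 3L),
                 left = c(2L, 3L, 1L), right = c(2L, 3L, 1L))
  a <- aperm(a, perm); sp <- sp[perm]
  if (wall %in% c("top", "right")) a <- a[, , rev(seq_len(dim(a)[3])), drop = FALSE]
  d <- dim(a)
  # Sobel-style gradient magnitude: central difference along the normal of
  # the laterally smoothed stack
  sm <- a
  for (k in seq_len(d[3])) sm[, , k] <- blur2d(a[, , k], 1)
  gz <- array(0, d)
  gz[, , 2:(d[3] - 1L)] <- abs(sm[, , 3:d[3]] - sm[, , 1:(d[3] - 2L)])
  thr <- EBImage::otsu(matrix(gz / max(gz), nrow = d[1])) * max(gz)
  bin <- gz > thr
  hmat <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    runs <- rle(bin[i, j, ])
    ends <- cumsum(runs$lengths)
    on <- which(runs$values)
    if (length(on) == 0L) next
    k <- on[length(on)]                     # innermost (lumen-facing) run
    hmat[i, j] <- (ends[k] + ends[k] - runs$lengths[k] + 1) / 2  # medial index
  }
  miss <- !is.finite(hmat)
  if (mean(miss) > max_missing)
    stop(sprintf("surface not resolvable: %.0f%% of cells have no skeleton position",
                 100 * mean(miss)))
  if (any(miss)) hmat <- fill_nearest(hmat)
  hmat <- (hmat - 1) * sp[3]
  hmat <- hmat - min(hmat)
  height_map(hmat, lateral_spacing = sp[1:2], wall = wall, missing = miss)
}

# Nearest-neighbour fill of NA cells in a matrix.
fill_nearest <- function(m) {
  bad <- which(!is.finite(m), arr.ind = TRUE)
  good <- which(is.finite(m), arr.ind = TRUE)
  vals <- m[good]
  for (r in seq_len(nrow(bad))) {
    d2 <- (good[, 1] - bad[r, 1])^2 + (good[, 2] - bad[r, 2])^2
    m[bad[r, 1], bad[r, 2]] <- vals[which.min(d2)]
  }
  m
}

#' Roughness statistics of a height map
#'
#' `h_mean` is the mean height with respect to the lowest profile points
#' (whose height is zero by construction); `R_q` is the root-mean-square
#' deviation about the mean plane (the standard rms-roughness definition).
#'
#' @param map a [height_map()].
#' @return A list with `R_q` and `h_mean`, um.
#' @export
roughness_stats <- function(map) {
  stopifnot(inherits(map, "height_map"))
  h <- map$heights
  list(h_mean = mean(h), R_q = sqrt(mean((h - mean(h))^2)))
}

#' Hump metrics of a height map
#'
#' Detects the dominant local maxima (cell-body humps) and reports their
#' height above the local base, full width at half prominence, and mean
#' nearest-neighbour spacing, each with a standard deviation.
#'
#' @param map a [height_map()].
#' @param n_measurements number of humps retained (strongest first).
#' @param min_prominence minimum peak height above the local base, as a
#'   fraction of the map range.
#' @param smooth_um Gaussian smoothing applied before peak detection, um
#'   (heights are measured on a lightly smoothed map so detection smoothing
#'   does not flatten the peaks).
#' @param min_separation_um minimum distance between two reported humps, um.
#' @return A list with `h`, `w`, `d` (each `c(mean, sd)`), the peak
#'   coordinates, and `n_peaks`. `d` is `NA` when fewer than 2 peaks exist.
#' @export
hump_metrics <- function(map, n_measurements = 20L, min_prominence = 0.25,
                         smooth_um = 2, min_separation_um = 8) {
  stopifnot(inherits(map, "height_map"))
  h <- map$heights
  d1 <- map$lateral_spacing[1]; d2 <- map$lateral_spacing[2]
  hs <- blur2d(h, smooth_um / mean(c(d1, d2)))
  hm <- blur2d(h, 0.5 / mean(c(d1, d2)))   # measurement map: noise-reduced only
  nr <- nrow(hs); nc <- ncol(hs)
  # local maxima over a 3x3 neighbourhood, interior only
  peaks <- NULL
  for (i in 2:(nr - 1)) {
    js <- which(hs[i, 2:(nc - 1)] == apply(rbind(
      hs[i - 1, 1:(nc - 2)], hs[i - 1, 2:(nc - 1)], hs[i - 1, 3:nc],
      hs[i, 1:(nc - 2)], hs[i, 2:(nc - 1)], hs[i, 3:nc],
      hs[i + 1, 1:(nc - 2)], hs[i + 1, 2:(nc - 1)], hs[i + 1, 3:nc]), 2, max)) + 1L
    if (length(js)) peaks <- rbind(peaks, cbind(i, js))
  }
  if (is.null(peaks)) stop("no local maxima found in height map")
  vals <- hs[peaks]
  rng <- diff(range(hs))
  keep <- vals >= min(hs) + min_prominence * rng
  peaks <- peaks[keep, , drop = FALSE]; vals <- vals[keep]
  if (nrow(peaks) == 0L) stop("no humps above the prominence threshold")
  ord <- order(vals, decreasing = TRUE)
  peaks <- peaks[ord, , drop = FALSE]
  # greedy non-maximum suppression: keep strongest peaks at least
  # min_separation_um apart
  keep <- integer(0)
  for (k in seq_len(nrow(peaks))) {
    if (length(keep) == 0L) { keep <- k; next }
    dd <- sqrt(((peaks[k, 1] - peaks[keep, 1]) * d1)^2 +
                 ((peaks[k, 2] - peaks[keep, 2]) * d2)^2)
    if (all(dd >= min_separation_um)) keep <- c(keep, k)
    if (length(keep) >= n_measurements) break
  }
  peaks <- peaks[keep, , drop = FALSE]
  # nearest-neighbour spacing (um)
  px <- (peaks[, 1] - 1) * d1; py <- (peaks[, 2] - 1) * d2
  np <- nrow(peaks)
  dvals <- NULL
  if (np >= 2) {
    dm <- as.matrix(stats::dist(cbind(px, py)))
    diag(dm) <- Inf
    dvals <- apply(dm, 1, min)
  }
  win <- if (np >= 2) stats::median(dvals) else
    min((nr - 1) * d1, (nc - 1) * d2) / 2
  hv <- wv <- numeric(np)
  for (k in seq_len(np)) {
    i <- peaks[k, 1]; j <- peaks[k, 2]
    ri <- max(1, i - round(win / d1)):min(nr, i + round(win / d1))
    rj <- max(1, j - round(win / d2)):min(nc, j + round(win / d2))
    base <- stats::quantile(hm[ri, rj], 0.05, names = FALSE)
    hv[k] <- hm[i, j] - base
    half <- base + hv[k] / 2
    wv[k] <- mean(c(half_width_1d(hm[, j], i, half) * d1,
                    half_width_1d(hm[i, ], j, half) * d2), na.rm = TRUE)
  }
  res <- list(
    h = c(mean = mean(hv), sd = stats::sd(hv)),
    w = c(mean = mean(wv, na.rm = TRUE), sd = stats::sd(wv, na.rm = TRUE)),
    d = if (np >= 2) c(mean = mean(dvals), sd = stats::sd(dvals))
        else c(mean = NA_real_, sd = NA_real_),
    peaks = cbind(x = px, y = py, height = hm[peaks]),
    n_peaks = np)
  res
}

# Width (in samples) of the peak at index i of profile y at level `half`,
# by linear interpolation; NA if not bracketed.
half_width_1d <- function(y, i, half) {
  n <- length(y)
  il <- i; while (il > 1 && y[il] > half) il <- il - 1L
  ir <- i; while (ir < n && y[ir] > half) ir <- ir + 1L
  if (y[il] > half || y[ir] > half) return(NA_real_)
  xl <- il + (half - y[il]) / (y[il + 1L] - y[il])
  xr <- ir - 1L + (half - y[ir - 1L]) / (y[ir] - y[ir - 1L])
  xr - xl
}

#' Effective no-slip boundary shift from small-slope surface roughness
#'
#' For laminar flow over a weakly rough wall (rms roughness `R_q` much
#' smaller than the roughness wavelength `d`), the wall appears
#' hydrodynamically smooth but shifted into the flow by
#' `delta = 2 * pi * R_q^2 / d`.
#'
#' @param r_q rms surface roughness, um (>= 0).
#' @param d typical roughness wavelength (hump spacing), um (> 0).
#' @return The boundary shift `delta`, um.
#' @export
boundary_shift <- function(r_q, d) {
  stopifnot(r_q >= 0)
  if (!is.numeric(d) || d <= 0) stop("roughness wavelength d must be positive")
  2 * pi * r_q^2 / d
}
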