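#' Specification of a synthetic endothelial surface
#'
#' The apical membrane is modelled as a flat cell periphery at `base_offset`
#' from the channel wall, decorated with Gaussian humps (emulating cell
#' bodies/nuclei) placed on a jittered square lattice. Defaults reproduce the
#' hump statistics measured in endothelialized microchannels: height 2.3 um,
#' width 15 um (FWHM), spacing 35 um, periphery 0.9 um.
#'
#' @param base_offset distance of the flat periphery from the wall, um.
#' @param hump_height hump amplitude, um.
#' @param hump_width hump full width at half maximum, um.
#' @param hump_spacing lattice spacing between humps, um (> 0).
#' @param hump_jitter lattice jitter as a fraction of the spacing, in `[0, 1)`.
#' @param seed integer seed for the jitter.
#' @return An object of class `surface_spec`.
#' @export
surface_spec <- function(base_offset = 0.9, hump_height = 2.3,
                         hump_width = 15, hump_spacing = 35,
                         hump_jitter = 0.2, seed = 1L) {
  stopifnot(base_offset >= 0, hump_height >= 0, hump_width >= 0,
            hump_spacing > 0, hump_jitter >= 0, hump_jitter < 1)
  structure(list(base_offset = base_offset, hump_height = hump_height,
                 hump_width = hump_width, hump_spacing = hump_spacing,
                 hump_jitter = hump_jitter, seed = as.integer(seed)),
            class = "surface_spec")
}

#' Specification of the fluorescent surface-layer shell
#'
#' Local shell thickness is drawn per lateral pixel as
#' `Normal(mean_thickness, thickness_sd)` clipped to be positive. Defaults
#' match the measured layer: 0.67 um mean, 0.2 um spread.
#'
#' @param mean_thickness mean shell thickness, um (> 0).
#' @param thickness_sd standard deviation of the local thickness, um.
#' @param intensity emitted intensity per unit shell occupancy (a.u.).
#' @param seed integer seed for the thickness field.
#' @return An object of class `shell_spec`.
#' @export
shell_spec <- function(mean_thickness = 0.67, thickness_sd = 0.2,
                       intensity = 1, seed = 1L) {
  stopifnot(mean_thickness > 0, thickness_sd >= 0, intensity > 0)
  structure(list(mean_thickness = mean_thickness, thickness_sd = thickness_sd,
                 intensity = intensity, seed = as.integer(seed)),
            class = "shell_spec")
}

#' Confocal noise model
#'
#' Poisson shot noise on a scaled intensity plus additive Gaussian read
#' noise, the standard model for photon-counting confocal detection.
#' `photon_scale = 0` disables shot noise.
#'
#' @param photon_scale expected photons per intensity unit (0 = noiseless).
#' @param read_sd standard deviation of additive read noise (a.u.).
#' @param seed integer seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(photon_scale = 200, read_sd = 0.01, seed = 1L) {
  stopifnot(photon_scale >= 0, read_sd >= 0)
  structure(list(photon_scale = photon_scale, read_sd = read_sd,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

apply_noise <- function(arr, noise) {
  if (is.null(noise)) return(arr)
  with_seed(noise$seed, {
    if (noise$photon_scale > 0)
      arr[] <- stats::rpois(length(arr), pmax(arr, 0) * noise$photon_scale) /
        noise$photon_scale
    if (noise$read_sd > 0)
      arr[] <- arr + stats::rnorm(length(arr), sd = noise$read_sd)
    arr
  })
}

# Sample the jittered-lattice hump field on a lateral grid. Coordinates of
# grid cell (i, j) are ((i-1)*d1, (j-1)*d2). Lattice extended one cell beyond
# the grid so edge humps contribute.
hump_field <- function(spec, n1, n2, d1, d2) {
  ext1 <- (n1 - 1) * d1; ext2 <- (n2 - 1) * d2
  s <- spec$hump_spacing
  centers1 <- seq(-s / 2, ext1 + s, by = s)
  centers2 <- seq(-s / 2, ext2 + s, by = s)
  grid <- expand.grid(c1 = centers1, c2 = centers2)
  jit <- spec$hump_jitter * s
  with_seed(spec$seed, {
    grid$c1 <- grid$c1 + stats::runif(nrow(grid), -jit, jit)
    grid$c2 <- grid$c2 + stats::runif(nrow(grid), -jit, jit)
  })
  sig <- spec$hump_width / (2 * sqrt(2 * log(2)))
  x1 <- (seq_len(n1) - 1) * d1
  x2 <- (seq_len(n2) - 1) * d2
  h <- matrix(0, n1, n2)
  if (spec$hump_height > 0 && sig > 0) {
    for (k in seq_len(nrow(grid))) {
      g1 <- exp(-(x1 - grid$c1[k])^2 / (2 * sig^2))
      g2 <- exp(-(x2 - grid$c2[k])^2 / (2 * sig^2))
      h <- h + spec$hump_height * outer(g1, g2)
    }
  }
  attr(h, "centers") <- grid[grid$c1 >= 0 & grid$c1 <= ext1 &
                               grid$c2 >= 0 & grid$c2 <= ext2, ]
  h
}

#' Generate a synthetic stack of a fluorescent surface layer on a wavy wall
#'
#' Rasterizes a fluorescent shell of locally varying thickness draped over
#' the membrane surface (periphery + humps), optionally blurs it with a PSF
#' and adds detection noise. Rasterization uses exact partial-volume coverage
#' along the wall normal, so sub-voxel thickness variation is represented
#' without aliasing.
#'
#' @param surface a [surface_spec()].
#' @param shell a [shell_spec()].
#' @param channel_side lateral extent of the generated wall patch, um.
#' @param voxel_spacing voxel spacing (x, y, z) in um; the lateral spacing
#'   matches the raster-scan resolution (0.225 um) by default.
#' @param psf optional `psf3d` for forward blurring (same voxel grid).
#' @param noise optional [noise_spec()].
#' @param wall which channel wall the patch belongs to: `"bottom"` (membrane
#'   height along z over the x-y grid) or `"left"` (membrane position along x
#'   over the y-z grid, as seen in XY planes crossing a lateral wall).
#' @param normal_margin empty space left beyond the shell along the wall
#'   normal, um.
#' @return A list with `stack` (an [image_stack3d()]) and `truth`, a list
#'   recording the membrane height and shell thickness on the lateral pixel
#'   grid together with the grid spacings and wall label.
#' @export
make_esl_stack <- function(surface, shell, channel_side = 30,
                           voxel_spacing = c(0.225, 0.225, 0.5),
                           psf = NULL, noise = NULL, wall = c("bottom", "left"),
                           normal_margin = 2) {
  stopifnot(inherits(surface, "surface_spec"), inherits(shell, "shell_spec"),
            channel_side > 0, length(voxel_spacing) == 3L)
  wall <- match.arg(wall)
  sp <- as.numeric(voxel_spacing)
  # generation grid: lateral axes (1, 2), wall normal along axis 3
  if (wall == "bottom") { dlat <- sp[1:2]; dn <- sp[3] }
  else { dlat <- sp[2:3]; dn <- sp[1] }
  n1 <- max(8L, round(channel_side / dlat[1]))
  n2 <- max(8L, round(channel_side / dlat[2]))
  hf <- hump_field(surface, n1, n2, dlat[1], dlat[2])
  zm <- surface$base_offset + hf
  tt <- with_seed(shell$seed,
                  matrix(stats::rnorm(n1 * n2, shell$mean_thickness,
                                      shell$thickness_sd), n1, n2))
  tt <- pmax(tt, 1e-3)
  if (shell$mean_thickness < dn)
    warning(sprintf("shell mean thickness (%.3g um) is below one voxel (%.3g um) along the wall normal",
                    shell$mean_thickness, dn))
  nn <- max(8L, ceiling((max(zm + tt) + normal_margin) / dn))
  # exact partial-volume coverage of [zm, zm + t] in voxel slab [(k-1)dn, k dn]
  arr <- array(0, c(n1, n2, nn))
  lo <- zm; hi <- zm + tt
  for (k in seq_len(nn)) {
    a <- (k - 1) * dn; b <- k * dn
    arr[, , k] <- pmax(0, pmin(hi, b) - pmax(lo, a)) / dn * shell$intensity
  }
  if (wall == "left") arr <- aperm(arr, c(3, 1, 2))   # normal becomes x
  st <- image_stack3d(arr, if (wall == "left") c(dn, dlat) else c(dlat, dn))
  if (!is.null(psf)) st <- convolve_stack(st, psf)
  st$data <- apply_noise(st$data, noise)
  list(stack = st,
       truth = list(height = zm, thickness = tt, wall = wall,
                    hump_centers = attr(hf, "centers"),
                    lateral_spacing = dlat, normal_spacing = dn))
}

#' Generate a synthetic fluorescent bead stack
#'
#' A solid fluorescent sphere of the given diameter, rasterized with 4x
#' supersampled partial-area coverage in-plane and point-sampled at each
#' z-plane (a confocal page samples the focal plane; axial blur is the PSF's
#' job), optionally blurred by a PSF and degraded with noise. Used to
#' validate the PSF/deconvolution step the same way latex calibration beads
#' are used on the microscope.
#'
#' @param diameter bead diameter in um (> 0).
#' @param psf optional `psf3d`.
#' @param voxel_spacing voxel spacing (x, y, z), um.
#' @param noise optional [noise_spec()].
#' @param margin empty margin around the bead, um.
#' @return An [image_stack3d()] with the bead centred in the volume.
#' @export
make_bead_stack <- function(diameter, psf = NULL,
                            voxel_spacing = c(0.225, 0.225, 0.5),
                            noise = NULL, margin = 1.5) {
  if (!is.numeric(diameter) || diameter <= 0)
    stop("bead diameter must be positive")
  sp <- as.numeric(voxel_spacing)
  half <- diameter / 2 + margin
  nd <- 2L * ceiling(half / sp) + 1L
  sub <- 4L
  offs <- ((seq_len(sub) - 0.5) / sub - 0.5)
  cover <- array(0, nd)
  centers <- lapply(1:3, function(k) (seq_len(nd[k]) - (nd[k] + 1) / 2) * sp[k])
  r2 <- (diameter / 2)^2
  for (ox in offs) for (oy in offs) {
    cx <- centers[[1]] + ox * sp[1]
    cy <- centers[[2]] + oy * sp[2]
    cover <- cover + (outer(outer(cx^2, cy^2, `+`), centers[[3]]^2, `+`) <= r2)
  }
  arr <- cover / sub^2
  st <- image_stack3d(arr, sp)
  if (!is.null(psf)) st <- convolve_stack(st, psf)
  st$data <- apply_noise(st$data, noise)
  st
}

#' FWHM of a bead image along one axis
#'
#' Line profile through the brightest voxel, measured with the same FWHM
#' estimator used for surface-layer profiles.
#'
#' @param stack an [image_stack3d()] containing a single bead.
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return FWHM in um.
#' @export
bead_fwhm <- function(stack, axis = 1L) {
  stopifnot(inherits(stack, "image_stack3d"), axis %in% 1:3)
  w <- which(stack$data == max(stack$data), arr.ind = TRUE)[1, ]
  line <- switch(axis,
                 stack$data[, w[2], w[3]],
                 stack$data[w[1], , w[3]],
                 stack$data[w[1], w[2], ])
  pos <- (seq_along(line) - 1) * stack$spacing[axis]
  fwhm(intensity_profile(pos, line))
}
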