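#' Generate a 3D confocal point-spread function
#'
#' Scalar Gaussian approximation of the confocal PSF: lateral standard
#' deviation `0.21 * lambda / NA` and axial standard deviation
#' `0.66 * lambda * n / NA^2`, sampled on the stack's voxel grid and
#' normalized to unit sum. The Gaussian model is adequate here because the
#' deconvolution step is validated end-to-end by bead recovery rather than by
#' PSF shape.
#'
#' @param numerical_aperture objective numerical aperture.
#' @param emission_wavelength emission wavelength in um (e.g. 0.52 for
#'   Alexa 488).
#' @param refractive_index refractive index of the immersion medium.
#' @param voxel_spacing numeric length-3 voxel spacing (x, y, z) in um.
#' @param extent odd integer vector (length 1 or 3): kernel size in voxels
#'   per axis; `NULL` chooses +-4 sigma per axis.
#' @return An object of class `psf3d` with fields `kernel`, `voxel_spacing`,
#'   `params`.
#' @export
generate_psf <- function(numerical_aperture, emission_wavelength = 0.52,
                         refractive_index = 1.518,
                         voxel_spacing = c(0.225, 0.225, 0.5),
                         extent = NULL) {
  stopifnot(numerical_aperture > 0,
            emission_wavelength > 0.3, emission_wavelength < 0.8,
            length(voxel_spacing) == 3L, all(voxel_spacing > 0))
  if (numerical_aperture >= refractive_index)
    stop("numerical aperture must be smaller than the immersion refractive index")
  sig_xy <- 0.21 * emission_wavelength / numerical_aperture
  sig_z <- 0.66 * emission_wavelength * refractive_index / numerical_aperture^2
  sig <- c(sig_xy, sig_xy, sig_z)
  if (is.null(extent)) {
    extent <- 2L * pmax(1L, ceiling(4 * sig / voxel_spacing)) + 1L
  } else {
    extent <- rep_len(as.integer(extent), 3L)
    if (any(extent %% 2L == 0L)) stop("extent must be odd")
  }
  ax <- lapply(1:3, function(k) {
    r <- (extent[k] - 1L) / 2L
    exp(-((-r:r) * voxel_spacing[k])^2 / (2 * sig[k]^2))
  })
  kernel <- outer(outer(ax[[1]], ax[[2]]), ax[[3]])
  kernel <- kernel / sum(kernel)
  structure(list(kernel = kernel, voxel_spacing = as.numeric(voxel_spacing),
                 params = list(numerical_aperture = numerical_aperture,
                               emission_wavelength = emission_wavelength,
                               refractive_index = refractive_index,
                               sigma_xy = sig_xy, sigma_z = sig_z)),
            class = "psf3d")
}

#' An ideal (delta-function) PSF
#'
#' @param voxel_spacing voxel spacing in um.
#' @return A `psf3d` whose kernel is a single unit voxel.
#' @export
delta_psf <- function(voxel_spacing = c(0.225, 0.225, 0.5)) {
  structure(list(kernel = array(1, c(1, 1, 1)),
                 voxel_spacing = as.numeric(voxel_spacing),
                 params = list(delta = TRUE)),
            class = "psf3d")
}

#' @export
print.psf3d <- function(x, ...) {
  d <- dim(x$kernel)
  cat(sprintf("<psf3d> %d x %d x %d voxels, sum = %.6f\n",
              d[1], d[2], d[3], sum(x$kernel)))
  invisible(x)
}
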