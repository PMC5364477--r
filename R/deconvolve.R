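# FFT-based 3D convolution and Richardson-Lucy deconvolution.

# Pad a 3D array reflectively by r = c(rx, ry, rz) voxels per side.
pad_reflect3d <- function(a, r) {
  idx <- function(n, rr) {
    if (rr == 0L) return(seq_len(n))
    c(pmin(n, pmax(1L, (rr + 1L):2L)), seq_len(n), pmax(1L, pmin(n, (n - 1L):(n - rr))))
  }
  a[idx(dim(a)[1], r[1]), idx(dim(a)[2], r[2]), idx(dim(a)[3], r[3]), drop = FALSE]
}

# Embed a centered kernel into an array of size dims with its center at [1,1,1]
# (circular layout), then FFT. Kernel dims must be odd and <= dims.
kernel_otf <- function(kernel, dims) {
  kd <- dim(kernel)
  if (any(kd > dims)) stop("PSF kernel larger than (padded) stack")
  big <- array(0, dims)
  r <- (kd - 1L) / 2L
  big[1:kd[1], 1:kd[2], 1:kd[3]] <- kernel
  for (ax in 1:3) {
    perm <- seq_len(dims[ax])
    shift <- r[ax]
    perm <- c(perm[(shift + 1L):dims[ax]], perm[seq_len(shift)])
    big <- switch(ax, big[perm, , , drop = FALSE], big[, perm, , drop = FALSE],
                  big[, , perm, drop = FALSE])
  }
  fft(big)
}

conv_otf <- function(a, otf) {
  re <- Re(fft(fft(a) * otf, inverse = TRUE)) / length(a)
  re
}

#' Convolve a stack with a PSF (forward blur model)
#'
#' Circular FFT convolution after reflective padding by one PSF half-width.
#' With a normalized PSF the total intensity is conserved (up to edge flux).
#'
#' @param stack an [image_stack3d()].
#' @param psf a `psf3d` sampled on the same voxel grid.
#' @return The blurred `image_stack3d`.
#' @export
convolve_stack <- function(stack, psf) {
  check_same_spacing(stack, psf)
  r <- (dim(psf$kernel) - 1L) %/% 2L
  ap <- pad_reflect3d(stack$data, r)
  otf <- kernel_otf(psf$kernel, dim(ap))
  out <- conv_otf(ap, otf)
  out <- out[(r[1] + 1):(r[1] + dim(stack$data)[1]),
             (r[2] + 1):(r[2] + dim(stack$data)[2]),
             (r[3] + 1):(r[3] + dim(stack$data)[3]), drop = FALSE]
  image_stack3d(out, stack$spacing)
}

check_same_spacing <- function(stack, psf) {
  stopifnot(inherits(stack, "image_stack3d"), inherits(psf, "psf3d"))
  if (any(abs(stack$spacing - psf$voxel_spacing) > 1e-9))
    stop("stack and PSF voxel spacings differ")
  invisible(TRUE)
}

#' Richardson-Lucy deconvolution of a 3D stack
#'
#' Iterative maximum-likelihood deconvolution under a Poisson noise model,
#' with reflective edge padding by one PSF half-width and an optional damping
#' of the multiplicative update (a mild Tikhonov-style regularization for
#' noisy data). Output is non-negative and conserves total intensity up to
#' edge flux.
#'
#' @param stack observed [image_stack3d()].
#' @param psf the `psf3d` to deconvolve with (same voxel grid).
#' @param iterations number of RL iterations (>= 1); default 15.
#' @param damping non-negative scalar; 0 (default) is plain RL, larger values
#'   shrink each multiplicative update towards 1.
#' @return The deconvolved `image_stack3d`.
#' @export
deconvolve <- function(stack, psf, iterations = 15L, damping = 0) {
  check_same_spacing(stack, psf)
  stopifnot(iterations >= 1, damping >= 0)
  kd <- dim(psf$kernel)
  if (all(kd == 1L)) return(stack)  # delta PSF: identity
  r <- (kd - 1L) %/% 2L
  obs <- pad_reflect3d(pmax(stack$data, 0), r)
  dims <- dim(obs)
  otf <- kernel_otf(psf$kernel, dims)
  kflip <- psf$kernel[rev(seq_len(kd[1])), rev(seq_len(kd[2])), rev(seq_len(kd[3])),
                      drop = FALSE]
  otf_t <- kernel_otf(kflip, dims)
  eps <- 1e-12 * max(obs, 1e-300)
  est <- pmax(obs, eps)
  for (it in seq_len(iterations)) {
    blur <- pmax(conv_otf(est, otf), eps)
    ratio <- obs / blur
    upd <- conv_otf(ratio, otf_t)
    if (damping > 0) upd <- 1 + (upd - 1) / (1 + damping)
    est <- pmax(est * upd, 0)
  }
  out <- est[(r[1] + 1):(r[1] + dim(stack$data)[1]),
             (r[2] + 1):(r[2] + dim(stack$data)[2]),
             (r[3] + 1):(r[3] + dim(stack$data)[3]), drop = FALSE]
  image_stack3d(out, stack$spacing)
}
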