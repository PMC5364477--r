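#' 3D confocal image stack
#'
#' Lightweight container for an XYZ intensity stack with physical voxel
#' spacing. Axis order of `data` is (x, y, z); spacing is in micrometres.
#'
#' @param data 3D numeric array of intensities, dimensions (nx, ny, nz).
#' @param spacing numeric length-3, voxel spacing in um along (x, y, z).
#' @return An object of class `image_stack3d`.
#' @export
image_stack3d <- function(data, spacing) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            is.numeric(spacing), length(spacing) == 3L, all(spacing > 0))
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "image_stack3d")
}

#' @export
print.image_stack3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack3d> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g um\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Time-lapse (XYT) image stack
#'
#' Container for a 2D time-lapse as acquired in fast line-scan confocal mode:
#' frames indexed by time along the third array dimension, with the streamwise
#' coordinate x along rows and the cross-channel coordinate y along columns.
#'
#' @param frames 3D numeric array (nx, ny, n_frames).
#' @param pixel_size pixel size in um (isotropic in-plane).
#' @param frame_rate acquisition rate in frames per second.
#' @return An object of class `timelapse_stack`.
#' @export
timelapse_stack <- function(frames, pixel_size, frame_rate) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L,
            pixel_size > 0, frame_rate > 0)
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_rate = frame_rate),
            class = "timelapse_stack")
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<timelapse_stack> %d x %d px, %d frames, %.3g um/px, %.4g fps\n",
              d[1], d[2], d[3], x$pixel_size, x$frame_rate))
  invisible(x)
}

# y coordinates (um) of the columns of a timelapse frame, origin at the image
# centre. Module-level functions that need a channel-axis origin re-reference
# via locate_walls().
frame_y_coords <- function(stack) {
  ny <- dim(stack$frames)[2]
  (seq_len(ny) - (ny + 1) / 2) * stack$pixel_size
}

#' Write an image stack as multi-page TIFF with a JSON metadata sidecar
#'
#' Pages are z-planes (for `image_stack3d`) or frames (for
#' `timelapse_stack`); intensities are stored as 32-bit float after an
#' affine rescaling into `[0, 1]` (offset and scale are recorded in the
#' sidecar so the round trip is lossless up to float precision).
#'
#' @param stack an `image_stack3d` or `timelapse_stack`.
#' @param path output TIFF path; the sidecar is written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (inherits(stack, "image_stack3d")) {
    arr <- stack$data
    meta <- list(kind = "xyz", spacing_um = stack$spacing)
  } else if (inherits(stack, "timelapse_stack")) {
    arr <- stack$frames
    meta <- list(kind = "xyt", pixel_size_um = stack$pixel_size,
                 frame_rate_hz = stack$frame_rate)
  } else stop("unsupported stack class")
  lo <- min(arr); hi <- max(arr)
  scale <- max(hi - lo, 1e-12)
  meta$intensity_offset <- lo
  meta$intensity_scale <- scale
  pages <- lapply(seq_len(dim(arr)[3]), function(k) (arr[, , k] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a stack written by [write_stack()]
#'
#' @param path TIFF path with its `.json` sidecar alongside.
#' @return An `image_stack3d` or `timelapse_stack`, per the sidecar metadata.
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  arr <- arr * meta$intensity_scale + meta$intensity_offset
  if (identical(meta$kind, "xyz"))
    image_stack3d(arr, meta$spacing_um)
  else
    timelapse_stack(arr, meta$pixel_size_um, meta$frame_rate_hz)
}
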