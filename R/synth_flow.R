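#' Specification of a synthetic red-blood-cell time-lapse experiment
#'
#' Defines the channel, flow and acquisition settings for the generator that
#' emulates autofluorescent RBC advected through a square microchannel imaged
#' at mid-height in fast line-scan mode. Lateral tracer positions are drawn
#' once per cell, either uniformly over the non-depleted core or from a
#' symmetric two-Gaussian mixture (the off-axis preferred paths seen in
#' confined blood flow).
#'
#' @param channel_width inner (wall-to-wall) channel width, um.
#' @param channel_height channel height, um.
#' @param flow_rate_per_channel volumetric flow rate in the imaged channel,
#'   uL/min.
#' @param depletion_width imposed near-wall depletion: no tracer centre lies
#'   within this distance of the walls, um (< channel_width / 2).
#' @param lateral_mode `"uniform"` or `"bimodal"` lateral distribution.
#' @param peak_separation distance between the two mixture means in bimodal
#'   mode, um (< channel_width - 2 * depletion_width).
#' @param peak_sd standard deviation of each mixture component, um.
#' @param tracer_radius effective disc radius of a rendered cell, um
#'   (default matches a 40 um^2 plan-view cell area).
#' @param tracer_count number of cells traversing during the sequence.
#' @param frame_rate acquisition rate, frames/s.
#' @param pixel_size pixel size, um.
#' @param tracer_intensity,wall_intensity rendered amplitudes (a.u.) of the
#'   cells and of the static stained-wall bands.
#' @param seed integer seed.
#' @return An object of class `flow_spec`.
#' @export
flow_spec <- function(channel_width = 27, channel_height = 27,
                      flow_rate_per_channel = 1 / 16,
                      depletion_width = 3.8,
                      lateral_mode = c("uniform", "bimodal"),
                      peak_separation = 8.5, peak_sd = 2.7,
                      tracer_radius = sqrt(40 / pi), tracer_count = 400L,
                      frame_rate = 300, pixel_size = 0.444,
                      tracer_intensity = 0.8, wall_intensity = 1,
                      seed = 1L) {
  lateral_mode <- match.arg(lateral_mode)
  stopifnot(channel_width > 0, channel_height > 0, flow_rate_per_channel > 0,
            depletion_width >= 0, depletion_width < channel_width / 2,
            frame_rate > 0, pixel_size > 0, tracer_radius > 0)
  if (lateral_mode == "bimodal" &&
      peak_separation >= channel_width - 2 * depletion_width)
    stop("peak_separation must fit inside the non-depleted core")
  structure(list(channel_width = channel_width, channel_height = channel_height,
                 flow_rate_per_channel = flow_rate_per_channel,
                 depletion_width = depletion_width, lateral_mode = lateral_mode,
                 peak_separation = peak_separation, peak_sd = peak_sd,
                 tracer_radius = tracer_radius,
                 tracer_count = as.integer(tracer_count),
                 frame_rate = frame_rate, pixel_size = pixel_size,
                 tracer_intensity = tracer_intensity,
                 wall_intensity = wall_intensity, seed = as.integer(seed)),
            class = "flow_spec")
}

# Draw lateral tracer positions per the spec; y_max bounds |y|.
draw_lateral <- function(flow, n) {
  y_max <- flow$channel_width / 2 - flow$depletion_width
  if (flow$lateral_mode == "uniform")
    return(stats::runif(n, -y_max, y_max))
  a <- flow$peak_separation / 2
  y <- numeric(n); got <- 0L
  while (got < n) {
    cand <- stats::rnorm(2L * (n - got), mean = sample(c(-a, a), 2L * (n - got),
                                                       replace = TRUE),
                         sd = flow$peak_sd)
    cand <- cand[abs(cand) <= y_max]
    take <- min(length(cand), n - got)
    if (take > 0) { y[(got + 1L):(got + take)] <- cand[seq_len(take)]; got <- got + take }
  }
  y
}

#' Generate a synthetic RBC time-lapse with ground-truth tracks
#'
#' Each tracer keeps a fixed lateral position and is advected streamwise at
#' the mid-height duct velocity for that position. Cells are rendered as
#' Gaussian-profile discs; two static bright bands at the wall positions
#' emulate the stained endothelial surface layer. Entry times/positions are
#' randomized so cells stream through the field of view continuously.
#'
#' @param flow a [flow_spec()].
#' @param duct a [duct_flow_model()] consistent with the channel dimensions.
#' @param duration sequence duration, s.
#' @param frame_px frame size in pixels, `c(nx, ny)` (streamwise, lateral).
#' @param noise optional [noise_spec()].
#' @return A list with `stack` (a [timelapse_stack()]) and `truth`: a data
#'   frame of every rendered position (`id`, `t` frame, `x`, `y` in um with
#'   y = 0 on the channel axis) plus per-cell true `y` and `speed`.
#' @export
make_rbc_timelapse <- function(flow, duct, duration = 3,
                               frame_px = c(512L, 100L), noise = NULL) {
  stopifnot(inherits(flow, "flow_spec"), inherits(duct, "duct_flow_model"),
            duration > 0)
  if (flow$tracer_count <= 0) stop("tracer_count must be positive")
  if (abs(duct$width - flow$channel_width) > 1e-6)
    stop("duct model width must match flow channel_width")
  px <- flow$pixel_size
  nx <- as.integer(frame_px[1]); ny <- as.integer(frame_px[2])
  lx <- nx * px
  n_frames <- max(2L, round(duration * flow$frame_rate))
  dt <- 1 / flow$frame_rate
  sigma <- flow$tracer_radius / sqrt(2)  # Gaussian spot, half-max at ~0.83 R
  gen <- with_seed(flow$seed, {
    y <- draw_lateral(flow, flow$tracer_count)
    v <- duct_velocity(duct, y, 0)
    # entry position at t = 0, uniform over the swept length so that cells
    # enter the field at a steady rate during the sequence
    x0 <- stats::runif(flow$tracer_count, -v * duration - 4 * sigma, lx + 4 * sigma)
    list(y = y, v = v, x0 = x0)
  })
  xc <- (seq_len(nx) - 0.5) * px
  yc <- (seq_len(ny) - (ny + 1) / 2) * px   # y = 0 on the channel axis
  wall_band <- flow$wall_intensity *
    (exp(-(yc - flow$channel_width / 2)^2 / (2 * 0.4^2)) +
     exp(-(yc + flow$channel_width / 2)^2 / (2 * 0.4^2)))
  frames <- array(0, c(nx, ny, n_frames))
  reach <- 3.5 * sigma
  truth <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    img <- matrix(rep(wall_band, each = nx), nx, ny)
    t_now <- (f - 1L) * dt
    x_now <- gen$x0 + gen$v * t_now
    vis <- which(x_now > -reach & x_now < lx + reach)
    for (i in vis) {
      ix <- which(abs(xc - x_now[i]) <= reach)
      iy <- which(abs(yc - gen$y[i]) <= reach)
      if (!length(ix) || !length(iy)) next
      img[ix, iy] <- img[ix, iy] + flow$tracer_intensity *
        outer(exp(-(xc[ix] - x_now[i])^2 / (2 * sigma^2)),
              exp(-(yc[iy] - gen$y[i])^2 / (2 * sigma^2)))
    }
    frames[, , f] <- img
    inside <- which(x_now >= 0 & x_now <= lx)
    if (length(inside))
      truth[[f]] <- data.frame(id = inside, t = f, x = x_now[inside],
                               y = gen$y[inside], speed = gen$v[inside])
  }
  frames <- apply_noise(frames, noise)
  truth <- do.call(rbind, truth)
  list(stack = timelapse_stack(frames, px, flow$frame_rate),
       truth = truth[order(truth$id, truth$t), ],
       cells = data.frame(id = seq_along(gen$y), y = gen$y, speed = gen$v))
}

#' Simulate the multi-plane RBC counting experiment
#'
#' Emulates the hematocrit protocol: cells are counted in a small number of
#' XY imaging planes spanning the channel height over an interval `dT`. The
#' channel height is tiled into one slab per plane and the number of cells
#' crossing each slab is Poisson with mean `number_density x slab flow rate x
#' dT`, where the number density follows from the imposed volume fraction and
#' the mean cell volume.
#'
#' @param duct a [duct_flow_model()].
#' @param hematocrit imposed RBC volume fraction, percent.
#' @param dT counting interval, s.
#' @param n_planes number of imaging planes spanning the height.
#' @param cell_volume mean RBC volume, fL.
#' @param seed integer seed.
#' @return A list with per-plane counts and the total count `N`.
#' @export
simulate_rbc_counts <- function(duct, hematocrit, dT = 3, n_planes = 7L,
                                cell_volume = 90, seed = 1L) {
  stopifnot(inherits(duct, "duct_flow_model"), hematocrit > 0, dT > 0,
            n_planes >= 1, cell_volume > 0)
  n_density <- (hematocrit / 100) / cell_volume  # cells/um^3 (1 fL = 1 um^3)
  edges <- seq(-duct$height / 2, duct$height / 2, length.out = n_planes + 1L)
  ys <- seq(-duct$width / 2, duct$width / 2, length.out = 121L)
  counts <- with_seed(seed, vapply(seq_len(n_planes), function(k) {
    zs <- seq(edges[k], edges[k + 1L], length.out = 41L)
    g <- expand.grid(y = ys, z = zs)
    v <- duct_velocity(duct, g$y, g$z)
    q_slab <- mean(v) * duct$width * (edges[k + 1L] - edges[k])  # um^3/s
    stats::rpois(1L, n_density * q_slab * dT)
  }, numeric(1)))
  list(counts = counts, N = sum(counts))
}
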