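#' Gaussian pre-blur of a time-lapse stack
#'
#' Smooths each frame with a normalized Gaussian so that a flowing cell
#' displays a single intensity maximum at its centre, the preparation step
#' for spot detection.
#'
#' @param stack a [timelapse_stack()].
#' @param radius_px Gaussian standard deviation in pixels (>= 1).
#' @return The blurred [timelapse_stack()].
#' @export
preblur <- function(stack, radius_px = 3) {
  stopifnot(inherits(stack, "timelapse_stack"), radius_px >= 1)
  timelapse_stack(blur_frames(stack$frames, radius_px), stack$pixel_size,
                  stack$frame_rate)
}

#' Locate the stained wall bands of a time-lapse
#'
#' The temporal mean projection shows the static fluorescent wall layer as
#' two bright bands; their ridge positions define the inner wall positions
#' and their midpoint defines the channel axis (the y origin used by the
#' tracking and flow-structure analyses).
#'
#' @param stack a [timelapse_stack()].
#' @return A list with `y_left`, `y_right` (um, image coordinates relative to
#'   the frame centre), `axis` (their midpoint) and `width` (their distance).
#' @export
locate_walls <- function(stack) {
  stopifnot(inherits(stack, "timelapse_stack"))
  prof <- colMeans(rowMeans(stack$frames, dims = 2))  # mean over x and t
  prof <- conv1d(prof, gauss_kernel1d(1))
  yc <- frame_y_coords(stack)
  mid <- (length(prof) + 1) / 2
  il <- which.max(prof[seq_len(floor(mid))])
  ir <- floor(mid) + which.max(prof[(floor(mid) + 1L):length(prof)])
  refine <- function(i) {
    if (i <= 1L || i >= length(prof)) return(0)
    quad_subpixel(prof[i - 1L], prof[i], prof[i + 1L])
  }
  y_left <- yc[il] + refine(il) * stack$pixel_size
  y_right <- yc[ir] + refine(ir) * stack$pixel_size
  list(y_left = y_left, y_right = y_right,
       axis = (y_left + y_right) / 2, width = y_right - y_left)
}

#' Detect flowing cells with a difference-of-Gaussians filter
#'
#' The static background (temporal mean, dominated by the stained wall
#' bands) is subtracted, each frame is filtered with a DoG band-pass tuned
#' to the spot diameter, and local maxima above the threshold are kept and
#' refined to sub-pixel precision by quadratic interpolation. Without the
#' background subtraction the wall bands systematically pull the lateral
#' position of near-wall cells. Pixels within `wall_margin` of the wall
#' bands are excluded.
#'
#' @param stack a (pre-blurred) [timelapse_stack()].
#' @param spot_diameter expected cell image diameter, um (>= 2 pixels).
#' @param threshold minimum DoG response (a.u.) for a detection.
#' @param walls optional output of [locate_walls()]; computed if `NULL`.
#' @param wall_margin exclusion margin around each wall band, um.
#' @param edge_margin exclusion margin at the streamwise frame edges, um,
#'   where partially visible cells bias the centroid; defaults to one spot
#'   radius.
#' @param subtract_static subtract the per-pixel temporal mean before
#'   filtering (requires >= 50 frames; default `TRUE`).
#' @return A data frame of detections: `t` (frame), `x`, `y` (um; y = 0 on
#'   the channel axis), `quality` (DoG response).
#' @export
detect <- function(stack, spot_diameter = 7.1, threshold = 0.02,
                   walls = NULL, wall_margin = 2.5,
                   edge_margin = spot_diameter / 2,
                   subtract_static = TRUE) {
  stopifnot(inherits(stack, "timelapse_stack"))
  px <- stack$pixel_size
  d_px <- spot_diameter / px
  if (d_px < 2) stop("spot_diameter must be at least 2 pixels")
  if (is.null(walls)) walls <- locate_walls(stack)
  s1 <- d_px / (2 * sqrt(2)); s2 <- 1.6 * s1
  yc <- frame_y_coords(stack)
  # accept only detections between the wall bands, clear of the band margin
  ok_y <- yc > walls$y_left + wall_margin & yc < walls$y_right - wall_margin
  nf <- dim(stack$frames)[3]
  work <- stack$frames
  if (subtract_static && nf >= 50)
    work <- work - as.vector(rowMeans(work, dims = 2))
  dogs <- blur_frames(work, s1) - blur_frames(work, s2)
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    dog <- dogs[, , f]
    nr <- nrow(dog); nc <- ncol(dog)
    core <- dog[2:(nr - 1), 2:(nc - 1)]
    ismax <- core >= dog[1:(nr - 2), 2:(nc - 1)] & core > dog[3:nr, 2:(nc - 1)] &
      core >= dog[2:(nr - 1), 1:(nc - 2)] & core > dog[2:(nr - 1), 3:nc] &
      core >= dog[1:(nr - 2), 1:(nc - 2)] & core > dog[3:nr, 3:nc] &
      core >= dog[3:nr, 1:(nc - 2)] & core > dog[1:(nr - 2), 3:nc] &
      core > threshold
    ismax[, !ok_y[2:(nc - 1)]] <- FALSE
    idx <- which(ismax, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    i <- idx[, 1] + 1L; j <- idx[, 2] + 1L
    # sub-pixel refinement: baseline-subtracted centroid over a small window
    # (robust on the broad DoG response, where a 3-point quadratic is easily
    # pulled by the slopes of neighbouring cells)
    wr <- 4L
    sx <- sy <- numeric(length(i))
    for (k in seq_along(i)) {
      ri <- max(1L, i[k] - wr):min(nr, i[k] + wr)
      rj <- max(1L, j[k] - wr):min(nc, j[k] + wr)
      wnd <- dog[ri, rj] - min(dog[ri, rj])
      tot <- sum(wnd)
      if (tot <= 0) next
      sx[k] <- sum(rowSums(wnd) * ri) / tot - i[k]
      sy[k] <- sum(colSums(wnd) * rj) / tot - j[k]
    }
    out[[f]] <- data.frame(t = f, x = (i - 0.5 + sx) * px,
                           y = yc[j] + sy * px - walls$axis,
                           quality = dog[cbind(i, j)])
  }
  dets <- do.call(rbind, out)
  if (is.null(dets)) dets <- data.frame(t = integer(), x = numeric(),
                                        y = numeric(), quality = numeric())
  lx <- dim(stack$frames)[1] * px
  dets <- dets[dets$x >= edge_margin & dets$x <= lx - edge_margin, ,
               drop = FALSE]
  attr(dets, "walls") <- walls
  dets
}

#' Link detections into trajectories (gated linear assignment)
#'
#' Frame-to-frame linking in the spirit of a simple LAP tracker: for each
#' consecutive frame pair the assignment minimizing the total squared
#' displacement is solved exactly (maximum-weight bipartite matching), with a
#' hard distance gate and no merging or splitting. Tracks may bridge up to
#' `max_gap` missed frames with a proportionally enlarged gate. Because the
#' channel flow is unidirectional, links with a backward streamwise
#' displacement are excluded by default (this prevents a track whose cell
#' has left the field of view from capturing the next cell upstream). Tracks
#' shorter than `min_length` detections are dropped.
#'
#' @param detections data frame from [detect()] (`t`, `x`, `y`).
#' @param max_displacement gate: maximum allowed displacement between
#'   consecutive frames, um.
#' @param max_gap maximum number of missed frames bridged within a track.
#' @param min_length minimum number of detections per retained track.
#' @param frame_rate frames per second, used to convert displacements into
#'   instantaneous velocities.
#' @param backward_tolerance largest backward streamwise displacement (um)
#'   still considered linkable; `Inf` disables the direction gate.
#' @return An object of class `rbc_tracks`: a list with `points` (detections
#'   labelled by `track`) and `tracks` (per-track `mean_y`, `mean_speed`,
#'   `speed_sd`, `length`).
#' @export
link <- function(detections, max_displacement = 12, max_gap = 0L,
                 min_length = 10L, frame_rate = 300,
                 backward_tolerance = 0.5) {
  stopifnot(is.data.frame(detections), max_displacement > 0, max_gap >= 0,
            min_length >= 1, frame_rate > 0)
  det <- detections[order(detections$t), , drop = FALSE]
  det$track <- NA_integer_
  if (nrow(det) == 0L)
    return(structure(list(points = det, tracks = data.frame()),
                     class = "rbc_tracks"))
  frames <- sort(unique(det$t))
  n_tracks <- 0L
  # active track state: id, last x, y, frame
  act <- data.frame(id = integer(), x = numeric(), y = numeric(), t = integer())
  rows_of <- split(seq_len(nrow(det)), det$t)
  for (f in frames) {
    rows <- rows_of[[as.character(f)]]
    cur <- det[rows, ]
    act <- act[f - act$t <= max_gap + 1L, , drop = FALSE]
    assigned <- rep(NA_integer_, nrow(cur))
    if (nrow(act) > 0L && nrow(cur) > 0L) {
      gap <- f - act$t
      dx <- outer(act$x, cur$x, function(a, b) b - a)
      d2 <- dx^2 + outer(act$y, cur$y, `-`)^2
      gate2 <- (gap * max_displacement)^2
      wmat <- matrix(0, nrow(act), nrow(cur))
      feas <- d2 < gate2 & dx > -backward_tolerance
      wmat[feas] <- (rep(gate2, ncol(d2))[feas] - d2[feas]) + 1e-9
      assigned <- match_bipartite(wmat)
    }
    for (k in seq_len(nrow(cur))) {
      if (!is.na(assigned[k])) {
        det$track[rows[k]] <- act$id[assigned[k]]
        act$x[assigned[k]] <- cur$x[k]; act$y[assigned[k]] <- cur$y[k]
        act$t[assigned[k]] <- f
      } else {
        n_tracks <- n_tracks + 1L
        det$track[rows[k]] <- n_tracks
        act <- rbind(act, data.frame(id = n_tracks, x = cur$x[k],
                                     y = cur$y[k], t = f))
      }
    }
  }
  summarize_tracks(det, min_length, frame_rate)
}

# Maximum-weight bipartite matching: returns, for each column (detection),
# the matched row (track) index or NA. Weights <= 0 are infeasible.
match_bipartite <- function(w) {
  nr <- nrow(w); nc <- ncol(w)
  edges <- which(w > 0, arr.ind = TRUE)
  if (nrow(edges) == 0L) return(rep(NA_integer_, nc))
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, nr), rep(TRUE, nc)),
    edges = as.vector(t(cbind(edges[, 1], nr + edges[, 2]))))
  m <- igraph::max_bipartite_match(g, weights = w[edges])$matching
  out <- m[(nr + 1L):(nr + nc)]
  out <- ifelse(is.na(out), NA_integer_, as.integer(out))
  out
}

summarize_tracks <- function(det, min_length, frame_rate) {
  keep_ids <- names(which(table(det$track) >= min_length))
  det <- det[det$track %in% as.integer(keep_ids), , drop = FALSE]
  if (nrow(det) == 0L)
    return(structure(list(points = det, tracks = data.frame(
      track = integer(), mean_y = numeric(), mean_speed = numeric(),
      speed_sd = numeric(), length = integer())), class = "rbc_tracks"))
  det <- det[order(det$track, det$t), ]
  stats_1 <- lapply(split(det, det$track), function(g) {
    dtf <- diff(g$t) / frame_rate
    v <- sqrt(diff(g$x)^2 + diff(g$y)^2) / dtf
    data.frame(track = g$track[1], mean_y = mean(g$y), mean_speed = mean(v),
               speed_sd = stats::sd(v), length = nrow(g))
  })
  structure(list(points = det, tracks = do.call(rbind, stats_1)),
            class = "rbc_tracks")
}

#' @export
print.rbc_tracks <- function(x, ...) {
  cat(sprintf("<rbc_tracks> %d tracks (%d linked detections), mean length %.1f frames\n",
              nrow(x$tracks), nrow(x$points),
              if (nrow(x$tracks)) mean(x$tracks$length) else 0))
  invisible(x)
}

#' Velocity profile and parabolic fit
#'
#' Builds the cross-channel velocity profile from per-track mean lateral
#' positions and speeds, and fits the Poiseuille-type parabola
#' `V(y) = V_max (1 - (y / y_wall)^2)` by least squares (linear in
#' `(1, y^2)`). Also reports the centreline statistic: mean and sd of track
#' speeds within +-1 um of the axis.
#'
#' @param tracks an `rbc_tracks` object (or a data frame with `mean_y`,
#'   `mean_speed`).
#' @param centerline_halfwidth half-width of the centreline band, um.
#' @param max_speed_cv quality gate: tracks whose frame-to-frame speed
#'   dispersion exceeds this fraction of their mean speed are dropped before
#'   fitting (advected tracers move at constant speed, so a large dispersion
#'   flags linking errors). `Inf` disables the gate.
#' @return An object of class `velocity_profile`: the profile points, the
#'   fit (`v_max`, `y_wall`, residual sd), and the centreline statistic.
#' @export
profile_and_fit <- function(tracks, centerline_halfwidth = 1,
                            max_speed_cv = 0.2) {
  pts <- if (inherits(tracks, "rbc_tracks")) tracks$tracks else tracks
  stopifnot(all(c("mean_y", "mean_speed") %in% names(pts)))
  if (is.finite(max_speed_cv) && "speed_sd" %in% names(pts))
    pts <- pts[!is.finite(pts$speed_sd) |
                 pts$speed_sd <= max_speed_cv * pts$mean_speed, , drop = FALSE]
  if (nrow(pts) < 20) stop("need at least 20 tracks to fit a profile")
  if (all(pts$mean_y >= 0) || all(pts$mean_y <= 0))
    stop("all tracks lie on one side of the channel axis; cannot fit")
  fit <- stats::lm(mean_speed ~ I(mean_y^2), data = pts)
  v_max <- unname(stats::coef(fit)[1])
  slope <- unname(stats::coef(fit)[2])
  y_wall <- if (slope < 0) sqrt(-v_max / slope) else NA_real_
  ctr <- pts$mean_speed[abs(pts$mean_y) <= centerline_halfwidth]
  structure(list(points = pts,
                 fit = list(v_max = v_max, y_wall = y_wall,
                            residual_sd = stats::sd(stats::residuals(fit))),
                 centerline = list(mean = mean(ctr), sd = stats::sd(ctr),
                                   n = length(ctr))),
            class = "velocity_profile")
}

#' @export
print.velocity_profile <- function(x, ...) {
  cat(sprintf("<velocity_profile> %d tracks; V_max = %.0f um/s, y_wall = %.2f um; centerline %.0f +/- %.0f um/s (n = %d)\n",
              nrow(x$points), x$fit$v_max, x$fit$y_wall,
              x$centerline$mean, x$centerline$sd, x$centerline$n))
  invisible(x)
}
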