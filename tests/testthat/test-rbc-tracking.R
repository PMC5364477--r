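# One small-scale experiment shared by several blocks in this file.
tl <- small_timelapse("uniform", seed = 11L, duration = 1.5, tracer_count = 250L)
tl_blur <- preblur(tl$stack, 3)
tl_det <- detect(tl_blur, 7.1, 0.005)
tl_tracks <- link(tl_det, max_displacement = 12, max_gap = 0, min_length = 10,
                  frame_rate = 300)

test_that("pre-blur is a normalized smoothing with a central maximum per cell", {
  const <- timelapse_stack(array(2.5, c(40, 30, 3)), 0.444, 300)
  expect_equal(preblur(const, 3)$frames, const$frames, tolerance = 1e-9)
  spot <- array(0, c(41, 41, 1)); spot[21, 21, 1] <- 1
  ps <- preblur(timelapse_stack(spot, 0.444, 300), 3)
  expect_equal(sum(ps$frames), 1, tolerance = 1e-6)
  expect_equal(which(ps$frames == max(ps$frames), arr.ind = TRUE)[1, 1:2],
               c(21, 21), ignore_attr = TRUE)
})

test_that("wall bands are located at the imposed wall positions", {
  w <- locate_walls(tl$stack)
  expect_equal(w$width, 27, tolerance = 0.02)
  expect_lt(abs(w$axis), 0.25)
})

test_that("detection finds the cells with sub-pixel accuracy and no blank-frame false positives", {
  # dilute stack: the detector is specified for separable spots
  sparse <- small_timelapse("uniform", seed = 17L, duration = 1,
                            tracer_count = 40L)
  sparse_det <- detect(preblur(sparse$stack, 3), 7.1, 0.005)
  tru <- sparse$truth
  matched <- 0L; n_checked <- 0L
  for (f in unique(sparse_det$t)) {
    d <- sparse_det[sparse_det$t == f, ]
    g <- tru[tru$t == f, ]
    # score truth positions that the detector can resolve: clear of the
    # frame edges and wall margin, and isolated from other cells (two
    # diameters; overlapping spots are outside the tracker's dilute regime)
    keep <- g$x > 6 & g$x < 256 * 0.444 - 6 & abs(g$y) < 9.3
    if (nrow(g) > 1) {
      dm <- as.matrix(dist(g[, c("x", "y")])); diag(dm) <- Inf
      keep <- keep & apply(dm, 1, min) > 15
    }
    g <- g[keep, ]
    if (!nrow(g)) next
    n_checked <- n_checked + nrow(g)
    for (i in seq_len(nrow(g))) {
      dd <- sqrt((d$x - g$x[i])^2 + (d$y - g$y[i])^2)
      if (length(dd) && min(dd) < 0.5 * 0.444) matched <- matched + 1L
    }
  }
  expect_gt(n_checked, 300)
  expect_gte(matched / n_checked, 0.95)

  # blank frames (walls + noise only): false-positive rate < 1 per 100 frames
  ny <- 100; nx <- 128; nf <- 200
  yc <- (seq_len(ny) - (ny + 1) / 2) * 0.444
  band <- exp(-(yc - 13.5)^2 / (2 * 0.4^2)) + exp(-(yc + 13.5)^2 / (2 * 0.4^2))
  fr <- array(rep(rep(band, each = nx), nf), c(nx, ny, nf))
  fr <- vesselchip:::apply_noise(fr, noise_spec(400, 0.01, seed = 6))
  blank <- preblur(timelapse_stack(fr, 0.444, 300), 3)
  dts <- detect(blank, 7.1, 0.005)
  expect_lt(nrow(dts), nf / 100)
})

test_that("linking recovers tracks of the expected length and exact speeds", {
  tk <- tl_tracks$tracks
  expect_gte(nrow(tk), 100)
  expect_true(all(tk$length >= 10))
  # a single isolated tracer yields one track at its exact speed
  one <- small_timelapse("uniform", seed = 3L, duration = 1, tracer_count = 1L)
  od <- detect(preblur(one$stack, 3), 7.1, 0.005)
  ot <- link(od, 12, 0, 5, 300)
  expect_equal(nrow(ot$tracks), 1L)
  expect_equal(ot$tracks$mean_speed, one$cells$speed, tolerance = 0.01)
  expect_equal(ot$tracks$mean_y, one$cells$y, tolerance = 0.25)
})

test_that("linking is invariant under within-frame relabeling of detections", {
  set.seed(1)
  shuffled <- tl_det[sample.int(nrow(tl_det)), ]
  t2 <- link(shuffled, 12, 0, 10, 300)
  key <- function(tr) {
    p <- tr$points[order(tr$points$track, tr$points$t), c("t", "x", "y")]
    sig <- vapply(split(p, tr$points$track[order(tr$points$track, tr$points$t)]),
                  function(g) paste(signif(c(g$t, g$x, g$y), 10), collapse = ","),
                  character(1))
    sort(unname(sig))
  }
  expect_equal(key(t2), key(tl_tracks))
})

test_that("crossing tracks separated laterally beyond the gate never swap", {
  # two constructed tracks that cross in x, 6 um apart in y, gate 4 um
  t <- 1:30
  a <- data.frame(t = t, x = 2 + 3.0 * t, y = rep(3, 30), quality = 1)
  b <- data.frame(t = t, x = 60 - 1.0 * t, y = rep(-3, 30), quality = 1)
  tr <- link(rbind(a, b), max_displacement = 4, max_gap = 0, min_length = 10,
             frame_rate = 300, backward_tolerance = Inf)
  expect_equal(nrow(tr$tracks), 2L)
  ys <- tapply(tr$points$y, tr$points$track, function(v) diff(range(v)))
  expect_true(all(ys == 0))                      # each track keeps its lane
  expect_equal(sort(tr$tracks$mean_speed), c(1, 3) * 300, tolerance = 1e-9)
})

test_that("the parabolic fit recovers exact and simulated profiles", {
  # exact parabola: machine-precision recovery
  y <- seq(-12, 12, length.out = 60)
  v <- 2950 * (1 - (y / 13.7)^2)
  fit <- profile_and_fit(data.frame(mean_y = y, mean_speed = v))
  expect_equal(fit$fit$v_max, 2950, tolerance = 1e-9)
  expect_equal(fit$fit$y_wall, 13.7, tolerance = 1e-9)
  expect_error(profile_and_fit(data.frame(mean_y = abs(y), mean_speed = v)),
               "one side")
  expect_error(profile_and_fit(data.frame(mean_y = y[1:10], mean_speed = v[1:10])),
               "at least 20")
  # simulated tracks: V_max within 3% of the duct model, symmetric apex
  vp <- profile_and_fit(tl_tracks)
  v0 <- duct_velocity(tl$duct, 0, 0)
  expect_lt(abs(vp$fit$v_max / v0 - 1), 0.03)
  fit2 <- lm(mean_speed ~ mean_y + I(mean_y^2), vp$points)
  apex <- -coef(fit2)[2] / (2 * coef(fit2)[3])
  expect_lt(abs(apex), 0.5)
  # per-track speed recovery RMSE < 3% of V_max (noiseless rendering)
  tk <- vp$points
  verr <- tk$mean_speed - duct_velocity(tl$duct, pmin(abs(tk$mean_y), 13.49), 0)
  expect_lt(sqrt(mean(verr^2)), 0.03 * v0)
})

test_that("centerline statistic mirrors imposed speed noise", {
  set.seed(7)
  y <- runif(400, -9.7, 9.7)
  v <- 2950 * (1 - (y / 13.7)^2) * (1 + rnorm(400, 0, 0.05))
  vp <- profile_and_fit(data.frame(mean_y = y, mean_speed = v))
  expect_equal(vp$centerline$sd / vp$centerline$mean, 0.05, tolerance = 0.5)
})
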