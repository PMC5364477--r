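test_that("seeded generation is bit-reproducible", {
  a <- flat_shell_sim(0.67, 0.2, noise = noise_spec(200, 0.01, seed = 4))
  b <- flat_shell_sim(0.67, 0.2, noise = noise_spec(200, 0.01, seed = 4))
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$thickness, b$truth$thickness)
  s1 <- small_timelapse(seed = 5L, duration = 0.2, tracer_count = 20L)
  s2 <- small_timelapse(seed = 5L, duration = 0.2, tracer_count = 20L)
  expect_identical(s1$stack$frames, s2$stack$frames)
  expect_identical(s1$truth, s2$truth)
})

test_that("a flat noiseless unblurred shell rasterizes to its exact FWHM", {
  sim <- flat_shell_sim(0.67, sd = 0)
  res <- measure_esl(sim$stack, 60, seed = 2)
  expect_true(all(abs(res$measurements$fwhm - 0.67) < 0.03))
  # ground truth always accompanies the stack
  expect_named(sim$truth, c("height", "thickness", "wall", "hump_centers",
                            "lateral_spacing", "normal_spacing"))
  expect_true(all(abs(sim$truth$thickness - 0.67) < 1e-9))
})

test_that("humped surfaces carry the imposed hump height in their ground truth", {
  sim <- make_esl_stack(surface_spec(base_offset = 0.9, hump_height = 2.3,
                                     hump_width = 15, hump_spacing = 35,
                                     hump_jitter = 0.1, seed = 7),
                        shell_spec(0.67, 0, seed = 8), channel_side = 80,
                        voxel_spacing = c(0.45, 0.45, 0.5), wall = "bottom")
  zr <- sim$truth$height - min(sim$truth$height)
  expect_equal(max(zr), 2.3, tolerance = 0.1)   # maxima ~ hump height
  expect_gt(nrow(sim$truth$hump_centers), 2)
})

test_that("sub-voxel shells warn and degenerate beads error", {
  expect_warning(flat_shell_sim(0.2, sd = 0), "below one voxel")
  # same shell is fine across the 0.5 um z-sampling of a bottom wall
  expect_warning(make_esl_stack(surface_spec(hump_height = 0, seed = 1),
                                shell_spec(0.3, 0, seed = 2),
                                channel_side = 5, wall = "bottom"),
                 "below one voxel")
  expect_error(make_bead_stack(0), "positive")
  expect_error(make_bead_stack(-1), "positive")
})

test_that("an ideal bead measures its own diameter under a delta PSF", {
  b <- make_bead_stack(0.5)
  expect_lt(abs(bead_fwhm(b, 1) - 0.5), 0.1125)  # half a lateral pixel
  expect_lt(abs(bead_fwhm(b, 2) - 0.5), 0.1125)
})

test_that("time-lapse ground truth obeys the imposed flow structure", {
  sim <- small_timelapse("uniform", seed = 11L, duration = 0.5,
                         tracer_count = 150L, depletion = 3.8)
  # no tracer centre inside the depleted layer
  expect_lt(max(abs(sim$cells$y)), 27 / 2 - 3.8 + 1e-9)
  # every cell advects at the mid-height duct speed for its lateral position
  expect_equal(sim$cells$speed,
               duct_velocity(sim$duct, sim$cells$y, 0), tolerance = 1e-12)
  # per-frame travel equals speed / frame rate; near the axis it approaches V_max
  g <- split(sim$truth, sim$truth$id)
  g <- g[vapply(g, nrow, 1L) >= 2]
  dx <- unlist(lapply(g, function(d) diff(d$x) / diff(d$t)))
  sp <- unlist(lapply(g, function(d) rep(d$speed[1] / 300, nrow(d) - 1L)))
  expect_equal(dx, sp, tolerance = 1e-12, ignore_attr = TRUE)
  vmax <- duct_velocity(sim$duct, 0, 0)
  expect_true(all(sim$cells$speed <= vmax + 1e-9))
  expect_error(make_rbc_timelapse(flow_spec(tracer_count = 0), sim$duct),
               "tracer_count|positive")
})

test_that("bimodal lateral draws have the imposed peak separation", {
  fl <- flow_spec(lateral_mode = "bimodal", peak_separation = 8.5, seed = 42)
  duct <- duct_flow_model(27, 27, 1 / 16)
  y <- vesselchip:::draw_lateral(fl, 20000)
  expect_lt(max(abs(y)), 27 / 2 - 3.8 + 1e-9)
  h <- hist(y, breaks = seq(-15, 15, 0.5), plot = FALSE)
  dens <- h$counts
  # modes of the mixture: one maximum per side, ~8.5 um apart (slightly
  # pulled together by component overlap), density at peak ~2x average
  mid <- length(dens) / 2
  pl <- h$mids[which.max(dens[1:mid])]
  pr <- h$mids[mid + which.max(dens[(mid + 1):length(dens)])]
  expect_lt(abs((pr - pl) - 8.5), 1)
  norm_dens <- (dens / 0.5) / (length(y) / 27)
  expect_lt(abs(max(norm_dens) - 2), 0.45)
})

test_that("stacks survive a TIFF + sidecar round trip", {
  sim <- flat_shell_sim(0.67, 0.1, noise = noise_spec(200, 0.01, seed = 4))
  p <- file.path(tempdir(), "shell.tif")
  write_stack(sim$stack, p)
  back <- read_stack(p)
  expect_s3_class(back, "image_stack3d")
  expect_equal(back$spacing, sim$stack$spacing)
  expect_equal(back$data, sim$stack$data, tolerance = 1e-6)
  tl <- small_timelapse(seed = 5L, duration = 0.2, tracer_count = 10L)
  p2 <- file.path(tempdir(), "movie.tif")
  write_stack(tl$stack, p2)
  back2 <- read_stack(p2)
  expect_s3_class(back2, "timelapse_stack")
  expect_equal(back2$frame_rate, 300)
  expect_equal(back2$frames, tl$stack$frames, tolerance = 1e-6)
  unlink(c(p, p2, paste0(c(p, p2), ".json")))
})
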