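test_that("roughness statistics follow their closed forms", {
  const <- height_map(matrix(1.3, 30, 30), c(0.5, 0.5))
  rs <- roughness_stats(const)
  expect_equal(rs$h_mean, 1.3)
  expect_equal(rs$R_q, 0)
  x <- seq(0, 8 * pi, length.out = 200)
  sine <- 0.7 + 0.4 * sin(x)
  msin <- height_map(matrix(rep(sine, 50), 200, 50), c(0.3, 0.3))
  rs2 <- roughness_stats(msin)
  expect_equal(rs2$h_mean, 0.7, tolerance = 1e-2)
  expect_equal(rs2$R_q, 0.4 / sqrt(2), tolerance = 1e-2)
  # invariance under lateral translation and 90-degree rotation
  m <- matrix(runif(900), 30, 30)
  m <- m - min(m)
  hm0 <- roughness_stats(height_map(m, c(0.5, 0.5)))
  hm_shift <- roughness_stats(height_map(m[c(11:30, 1:10), ], c(0.5, 0.5)))
  hm_rot <- roughness_stats(height_map(t(m)[30:1, ], c(0.5, 0.5)))
  expect_equal(hm_shift, hm0)
  expect_equal(hm_rot, hm0)
})

test_that("a flat membrane extracts to a zero height map", {
  sim <- flat_shell_sim(0.67, sd = 0)
  hm <- extract_surface(sim$stack, "left")
  expect_equal(min(hm$heights), 0)
  expect_lt(sqrt(mean(hm$heights^2)), sim$stack$spacing[1] / 2)
})

test_that("humped surfaces are recovered with their metrics", {
  surf <- surface_spec(base_offset = 0.9, hump_height = 2.3, hump_width = 15,
                       hump_spacing = 35, hump_jitter = 0.2, seed = 7)
  sim <- make_esl_stack(surf, shell_spec(0.67, 0.1, seed = 8),
                        channel_side = 100, voxel_spacing = c(0.45, 0.45, 0.5),
                        wall = "bottom")
  hm <- extract_surface(sim$stack, "bottom")
  expect_equal(min(hm$heights), 0)
  expect_lte(mean(hm$missing), 0.2)
  # map maxima ~ hump height above the (zero-referenced) periphery
  expect_lt(abs(max(hm$heights) - 2.3), 0.3 + 3 * 0.1)
  rec <- hump_metrics(hm, 20)
  tru <- hump_metrics(height_map(sim$truth$height - min(sim$truth$height),
                                 sim$truth$lateral_spacing), 20)
  expect_lt(abs(rec$h[1] - tru$h[1]), 0.5)       # reported spread on h
  expect_lt(abs(rec$w[1] - tru$w[1]), 5)         # reported spread on w
  expect_lt(abs(rec$d[1] - tru$d[1]), 1)         # spacing from same peaks
  # spacing against the generator's realized hump centres
  ctr <- sim$truth$hump_centers
  dm <- as.matrix(dist(ctr)); diag(dm) <- Inf
  expect_lt(abs(rec$d[1] - mean(apply(dm, 1, min))), sd(apply(dm, 1, min)))
  # roughness in the reported band for these generation settings
  rs <- roughness_stats(hm)
  expect_gt(rs$R_q, 0.5); expect_lt(rs$R_q, 0.7)
})

test_that("ideal bumps yield exact hump metrics", {
  x <- (0:132) * 0.45
  s <- 15 / (2 * sqrt(2 * log(2)))
  one <- 2.3 * outer(exp(-(x - 30)^2 / (2 * s^2)), exp(-(x - 30)^2 / (2 * s^2)))
  r1 <- hump_metrics(height_map(one, c(0.45, 0.45)), 5)
  expect_equal(r1$h[["mean"]], 2.3, tolerance = 0.02)
  expect_equal(r1$w[["mean"]], 15, tolerance = 0.02)
  expect_true(is.na(r1$d[["mean"]]))             # single peak: no spacing
  two <- 2.3 * (outer(exp(-(x - 15)^2 / (2 * s^2)), exp(-(x - 30)^2 / (2 * s^2))) +
                outer(exp(-(x - 50)^2 / (2 * s^2)), exp(-(x - 30)^2 / (2 * s^2))))
  r2 <- hump_metrics(height_map(two, c(0.45, 0.45)), 5)
  expect_equal(r2$n_peaks, 2L)
  expect_equal(r2$d[["mean"]], 35, tolerance = 0.01)
})

test_that("left and right walls give mirrored height maps", {
  surf <- surface_spec(base_offset = 0.9, hump_height = 1.5, hump_width = 8,
                       hump_spacing = 15, hump_jitter = 0.2, seed = 3)
  sim <- make_esl_stack(surf, shell_spec(0.5, 0, seed = 4), channel_side = 30,
                        wall = "left")
  hml <- extract_surface(sim$stack, "left")
  mirrored <- image_stack3d(sim$stack$data[rev(seq_len(dim(sim$stack$data)[1])), , ],
                            sim$stack$spacing)
  hmr <- extract_surface(mirrored, "right")
  expect_equal(hmr$heights, hml$heights)
})

test_that("boundary shift reproduces the printed value and its scalings", {
  expect_equal(boundary_shift(0.6, 35), 0.065, tolerance = 0.01)
  expect_equal(signif(boundary_shift(0.6, 35), 2), 0.065)
  expect_equal(boundary_shift(0, 35), 0)
  expect_equal(boundary_shift(1.2, 35), 4 * boundary_shift(0.6, 35))
  expect_equal(boundary_shift(0.6, 70), boundary_shift(0.6, 35) / 2)
  expect_error(boundary_shift(0.6, 0), "positive")
})
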