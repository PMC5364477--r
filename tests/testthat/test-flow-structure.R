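test_that("temporal projections separate static walls from moving cells", {
  static <- timelapse_stack(array(rep(runif(40 * 30), 60), c(40, 30, 60)),
                            0.444, 300)
  pr <- t_project(static)
  expect_true(all(pr$std_image == 0))
  alt <- timelapse_stack(array(rep(c(0, 1), each = 40 * 30, length.out = 40 * 30 * 60),
                               c(40, 30, 60)), 0.444, 300)
  pa <- t_project(alt)
  expect_true(all(abs(pa$mean_image - 0.5) < 1e-12))
  expect_true(all(abs(pa$std_image - 0.5) < 1e-12))
  expect_error(t_project(timelapse_stack(array(0, c(4, 4, 10)), 0.444, 300)),
               "at least 50")
  # synthetic movie: walls only in the mean image, cell paths only in std
  tl <- small_timelapse("uniform", seed = 13L, duration = 1, tracer_count = 150L)
  pr2 <- t_project(tl$stack)
  yc <- (seq_len(ncol(pr2$mean_image)) - (ncol(pr2$mean_image) + 1) / 2) * 0.444
  at_wall <- which.min(abs(yc - 13.5))
  at_axis <- which.min(abs(yc))
  mean_prof <- colMeans(pr2$mean_image)
  std_prof <- colMeans(pr2$std_image)
  expect_gt(mean_prof[at_wall], 5 * mean_prof[at_axis])
  expect_gt(std_prof[at_axis], 4 * std_prof[at_wall])
})

test_that("cell-free layer is recovered from the projections", {
  tl <- small_timelapse("uniform", seed = 13L, duration = 1.5, tracer_count = 250L)
  cf <- cfl_thickness(t_project(tl$stack), n_positions = 8)
  expect_equal(nrow(cf), 8L)
  expect_true(all(cf$w_rbc <= cf$w_ch))
  expect_equal(cf$h_dep, (cf$w_ch - cf$w_rbc) / 2)
  expect_equal(mean(cf$w_ch), 27, tolerance = 0.01)
  expect_lt(abs(attr(cf, "h_dep_mean") - 3.8), 0.5)
  # a column filling the channel leaves no measurable depletion
  # (full-length acquisition: the near-wall cells are slow and sparse, so
  # the column edge needs the full transit statistics)
  flf <- flow_spec(lateral_mode = "uniform", depletion_width = 0.05, seed = 13L)
  ductf <- duct_flow_model(27, 27, 1 / 16)
  simf <- make_rbc_timelapse(flf, ductf)
  cff <- cfl_thickness(t_project(simf$stack), n_positions = 8)
  expect_lt(abs(attr(cff, "h_dep_mean")), 0.5)
  # no wall bands -> missing wall peak error
  blank <- timelapse_stack(array(runif(40 * 30 * 60, 0, 1e-4), c(40, 30, 60)),
                           0.444, 300)
  expect_error(cfl_thickness(t_project(blank)), "wall peak")
})

test_that("total cell-free layer combines depletion and surface layer", {
  expect_equal(3.8 + 0.67, 4.47, tolerance = 1e-12)   # printed: 4.5 +/- 0.7
  expect_lt(abs((3.8 + 0.67) - 4.5), 0.7)
})

test_that("lateral distribution is normalized and finds the imposed modes", {
  # uniform positions: density ~ 1 in occupied bins
  set.seed(5)
  yu <- runif(4000, -9.7, 9.7)
  ld <- lateral_distribution(data.frame(mean_y = yu), mean_width = 2 * 9.7)
  occ <- ld$density[abs(ld$bin_centers) < 9]
  expect_true(all(abs(occ - 1) < 0.15))
  # normalization identity: sum(density * dy) / mean_width = 1 over counted tracks
  expect_equal(sum(ld$density * 1) / 19.4, 1, tolerance = 1e-9)
  # exclusion bookkeeping
  ld2 <- lateral_distribution(data.frame(mean_y = c(yu, 40, -40)), 19.4)
  expect_equal(ld2$n_excluded, 2L)
  expect_equal(length(ld2$bin_centers), 30L)
  expect_equal(diff(ld2$bin_centers)[1], 1)
  # bimodal: two maxima at the imposed separation, ~2x average contrast
  fl <- flow_spec(lateral_mode = "bimodal", peak_separation = 8.5, seed = 42)
  yb <- vesselchip:::draw_lateral(fl, 3000)
  ldb <- lateral_distribution(data.frame(mean_y = yb), mean_width = 27)
  expect_equal(length(ldb$peaks$positions), 2L)
  expect_lt(abs(ldb$peaks$separation - 8.5), 1)
  expect_lt(abs(ldb$peaks$contrast - 2), 0.5)
})

test_that("hematocrit estimator applies the counting formula exactly", {
  ht <- hematocrit(850, 90, 1, 16, 3)
  expect_equal(ht$ht, 850 * 90e-9 / ((1 / 16 / 60) * 3) * 100)
  expect_equal(ht$ht, 2.448, tolerance = 1e-3)        # printed: 2.5 +/- 0.5
  expect_equal(hematocrit(0, 90, 1, 16, 3)$ht, 0)
  expect_equal(hematocrit(850, 90, 1, 16, 6)$ht, ht$ht / 2)
  expect_equal(ht$Q_channel, 1 / 16)
})

test_that("multi-plane counting recovers an imposed volume fraction", {
  duct <- duct_flow_model(30, 30, 1 / 16)
  for (s in c(9L, 10L)) {
    cnt <- simulate_rbc_counts(duct, hematocrit = 2.5, dT = 3, n_planes = 7,
                               seed = s)
    est <- hematocrit(cnt$N, 90, 1, 16, 3)
    expect_lt(abs(est$ht / 2.5 - 1), 0.2)
    expect_equal(sum(cnt$counts), cnt$N)
  }
})

test_that("cumulated-area bookkeeping matches the printed figures", {
  a20 <- cumulated_area_check(400, 40, 20)
  a30 <- cumulated_area_check(400, 40, 30)
  expect_equal(a20$area, 3.2e5)
  expect_equal(a30$area, 4.8e5)
  expect_gt(a20$ratio, 45); expect_lt(a30$ratio, 70)
  expect_equal(cumulated_area_check(0, 40, 25)$area, 0)
})
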