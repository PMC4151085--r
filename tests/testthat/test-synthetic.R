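test_that("generators are bit-reproducible under a fixed seed", {
  f1 <- make_fiber_image(30, 40, 10, size = 96, seed = 11)
  f2 <- make_fiber_image(30, 40, 10, size = 96, seed = 11)
  expect_identical(f1$image, f2$image)
  expect_identical(f1$fiber_angles, f2$fiber_angles)

  t1 <- make_track_mixture(40, seed = 3)
  t2 <- make_track_mixture(40, seed = 3)
  expect_identical(t1$tracks, t2$tracks)

  a1 <- make_anchoring_angles(50, seed = 9)
  expect_identical(a1, make_anchoring_angles(50, seed = 9))
})

test_that("fiber truth angles follow the requested axial distribution", {
  f <- make_fiber_image(800, mu_deg = 30, kappa = 20, size = 96, seed = 2)
  expect_true(all(f$fiber_angles >= 0 & f$fiber_angles < 180))
  expect_true(all(f$image >= 0))
  mu_hat <- oracle_axial_mean(f$fiber_angles)
  expect_lt(abs(mu_hat - 30), 2)

  # kappa = 0: angles uniform on [0, 180) -> tiny axial resultant
  f0 <- make_fiber_image(2000, mu_deg = 30, kappa = 0, size = 96, seed = 2)
  expect_lt(oracle_resultant(f0$fiber_angles, axial = TRUE), 0.08)
})

test_that("fiber generator rejects invalid parameters", {
  expect_error(make_fiber_image(10, size = 32), "size")
  expect_error(make_fiber_image(10, noise_sd = -1), "noise_sd")
  expect_error(make_fiber_image(10, kappa = -2), "kappa")
})

test_that("track mixture honors fractions, modes and timing", {
  tm <- make_track_mixture(200, 0.5, 0.3, 0.2, n_frames = 6,
                           frame_interval_s = 5, seed = 7)
  expect_equal(as.integer(table(tm$labels)[c("stuck", "transcytotic", "wandering")]),
               c(40L, 100L, 60L))
  expect_equal(unique(diff(tm$tracks$t_seconds[tm$tracks$track_id == 1])), 5)
  stuck <- tm$tracks[tm$tracks$truth_label == "stuck", ]
  expect_equal(as.numeric(tapply(stuck$x, stuck$track_id,
                                 function(v) max(abs(diff(v))))),
               rep(0, 40))
  expect_error(make_track_mixture(10, 0.5, 0.3, 0.1), "sum to 1")
  expect_error(make_track_mixture(10, n_frames = 1), "n_frames")
})

test_that("transcytotic drift direction follows p_distal", {
  tm <- make_track_mixture(400, 1, 0, 0, p_distal = 1, seed = 5)
  net <- tapply(seq_len(nrow(tm$tracks)), tm$tracks$track_id, function(ix) {
    tr <- tm$tracks[ix, ]
    tr$x[nrow(tr)] - tr$x[1]
  })
  expect_true(all(net > 0))
})

test_that("anchoring angle mixtures land in the requested modes", {
  a <- make_anchoring_angles(2000, modes_deg = c(0, 180), kappa = 20, seed = 1)
  expect_true(all(a >= 0 & a < 360))
  # axial concentration on the P-D axis, no net direction
  expect_gt(oracle_resultant(a, axial = TRUE), 0.8)
  expect_lt(oracle_resultant(a), 0.1)
  u <- make_anchoring_angles(2000, modes_deg = 0, kappa = 0, seed = 1)
  expect_lt(oracle_resultant(u), 0.06)
  expect_length(make_anchoring_angles(1, seed = 2), 1)
  expect_error(make_anchoring_angles(5, modes_deg = numeric(0)), "modes")
})

test_that("dot-membrane pair encodes the requested proximal offset", {
  g <- hex_grid(4, 6)
  pr <- make_dot_membrane_pair(g, offset_px = 4, cell_px = 20, seed = 1)
  expect_equal(pr$apothem_px, 10)
  expect_equal(dim(pr$dots), dim(pr$membrane))
  # dot maxima sit offset_px proximal to the stored centroids
  i <- which(g$row == 2 & g$col == 3)
  win <- 8
  ys <- round(pr$centers$y[i]) + (-win:win)
  xs <- round(pr$centers$x[i]) + (-win:win)
  sub <- pr$dots[ys, xs]
  peak <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  expect_equal(xs[peak["col"]], round(pr$centers$x[i]) - 4, tolerance = 1)
  expect_error(make_dot_membrane_pair(g, offset_px = 11, cell_px = 20),
               "half a cell")
  # same params, two seeds: identical geometry (noise-free channels equal)
  pr2 <- make_dot_membrane_pair(g, offset_px = 4, cell_px = 20, seed = 99)
  expect_identical(pr$membrane, pr2$membrane)
})

test_that("von Mises sampler concentrates correctly", {
  set.seed(1)
  x <- rvonmises(4000, mu_deg = 120, kappa = 10)
  expect_lt(abs(circ_mean(x)$mean_deg - 120), 3)
  expect_gt(circ_mean(x)$R, 0.9)
  set.seed(1)
  expect_lt(circ_mean(rvonmises(4000, 0, 0))$R, 0.06)
  expect_error(rvonmises(5, 0, -1), "kappa")
})
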