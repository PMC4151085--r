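test_that("self-correlation peaks at zero with r = 1", {
  set.seed(1)
  a <- oracle_shifted_pair(offset = 0)$a
  pr <- shift_correlation(a, a, max_shift = 8)
  expect_equal(pr$shifts[which.max(pr$r)], 0)
  expect_equal(max(pr$r), 1)
  expect_true(all(pr$r >= -1 & pr$r <= 1, na.rm = TRUE))
})

test_that("constructed translations are recovered within 0.5 px", {
  for (o in 1:8) {
    pp <- oracle_shifted_pair(w = 80, h = 50, offset = o, seed = o)
    pr <- shift_correlation(pp$a, pp$b, max_shift = 12)
    best <- pr$peaks$shift_refined[which.max(pr$peaks$r)]
    expect_lt(abs(best - o), 0.5)
  }
})

test_that("proximal dots give |A| < |B| and a symmetric A-P control", {
  pair <- make_dot_membrane_pair(hex_grid(6, 8), offset_px = 4,
                                 cell_px = 20, seed = 2)
  pr <- shift_correlation(pair$dots, pair$membrane, axis = "PD",
                          max_shift = 20)
  expect_false(is.na(pr$A))
  expect_false(is.na(pr$B))
  expect_lt(abs(pr$A), abs(pr$B))
  # noise-free geometry: |A| ~ apothem - offset, |B| ~ apothem + offset
  expect_equal(abs(pr$A), pair$apothem_px - 4, tolerance = 0.75)
  expect_equal(abs(pr$B), pair$apothem_px + 4, tolerance = 0.75)

  ctrl <- orthogonal_control(pair$dots, pair$membrane, max_shift = 20)
  expect_lt(abs(abs(ctrl$A) - abs(ctrl$B)), 1)

  # zero offset: P-D peaks symmetric too
  p0 <- make_dot_membrane_pair(hex_grid(6, 8), offset_px = 0,
                               cell_px = 20, seed = 2)
  pr0 <- shift_correlation(p0$dots, p0$membrane, max_shift = 20)
  expect_lt(abs(abs(pr0$A) - abs(pr0$B)), 1)
})

test_that("dots offset in y are detected by the A-P profile", {
  g <- hex_grid(6, 8)
  pr <- make_dot_membrane_pair(g, offset_px = 4, axis_deg = 90,
                               cell_px = 20, seed = 3)
  ctrl <- orthogonal_control(pr$dots, pr$membrane, max_shift = 20)
  expect_gt(abs(abs(ctrl$B) - abs(ctrl$A)), 2)
})

test_that("swapping channels mirrors the profile", {
  pp <- oracle_shifted_pair(offset = 3, seed = 5)
  p1 <- shift_correlation(pp$a, pp$b, max_shift = 10)
  p2 <- shift_correlation(pp$b, pp$a, max_shift = 10)
  expect_equal(p1$r, rev(p2$r), tolerance = 1e-10)
})

test_that("r is invariant to affine intensity rescaling", {
  pp <- oracle_shifted_pair(offset = 2, seed = 6)
  p1 <- shift_correlation(pp$a, pp$b, max_shift = 6)
  p2 <- shift_correlation(3 * pp$a + 7, 0.2 * pp$b - 1, max_shift = 6)
  expect_equal(p1$r, p2$r, tolerance = 1e-10)
})

test_that("masks restrict the correlation support", {
  pp <- oracle_shifted_pair(w = 60, h = 40, offset = 0, seed = 7)
  mask <- matrix(FALSE, 40, 60)
  mask[, 1:30] <- TRUE
  pr <- shift_correlation(pp$a, pp$b, max_shift = 5, mask = mask)
  expect_false(anyNA(pr$r))
  # constant channel: zero-variance overlaps recorded as missing
  prc <- shift_correlation(matrix(1, 40, 60), pp$b, max_shift = 5)
  expect_true(all(is.na(prc$r)))
  expect_error(shift_correlation(pp$a, pp$b[, 1:30], max_shift = 5), "shape")
  expect_error(shift_correlation(pp$a, pp$b, max_shift = 40), "max_shift")
})
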