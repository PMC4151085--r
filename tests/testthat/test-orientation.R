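make_grating <- function(size, angle_deg, freq = 0.15) {
  xy <- expand.grid(y = seq_len(size), x = seq_len(size))
  a <- angle_deg * pi / 180
  # stripes ALONG angle_deg: phase varies orthogonally to the stripe axis
  matrix(cos(2 * pi * freq * (-xy$x * sin(a) + xy$y * cos(a))), size)
}

test_that("structure tensor recovers grating orientation to half a degree", {
  for (ang in c(30, 75, 140)) {
    of <- structure_tensor_orientation(make_grating(96, ang))
    hi <- of$coherence > 0.9
    expect_gt(mean(hi), 0.5)
    est <- oracle_axial_mean(of$theta[hi])
    d <- min(abs(est - ang), 180 - abs(est - ang))
    expect_lt(d, 0.5)
  }
})

test_that("theta is equivariant under 90-degree image rotation", {
  img <- make_fiber_image(40, 25, 15, size = 96, noise_sd = 0, seed = 3)$image
  of1 <- structure_tensor_orientation(img)
  # rotate image by 90 deg counterclockwise in array terms
  of2 <- structure_tensor_orientation(t(img)[ncol(img):1, ])
  hi <- of1$coherence > 0.5
  m1 <- oracle_axial_mean(of1$theta[hi])
  m2 <- oracle_axial_mean(of2$theta[t(hi)[ncol(img):1, ]])
  d <- abs(((m2 - m1 + 90) %% 180) - 90)
  expect_lt(abs(d - 90) %% 90, 1)  # shifted by 90 mod 180
})

test_that("white noise yields near-zero coherence, constant image zero", {
  set.seed(4)
  of <- structure_tensor_orientation(matrix(rnorm(96^2), 96))
  expect_lt(mean(of$coherence), 0.25)
  ofc <- structure_tensor_orientation(matrix(1, 64, 64))
  expect_equal(max(ofc$coherence), 0)
})

test_that("orientation histogram is normalized, exhaustive and defaulted", {
  of <- structure_tensor_orientation(make_grating(96, 30))
  oh <- orientation_histogram(of)
  expect_equal(oh$n_bins, 36)
  expect_equal(oh$bin_width, 5)
  expect_equal(sum(oh$weights), 1)
  expect_true(all(oh$weights >= 0))
  # mode within one bin of the truth
  expect_lt(abs(oh$mid_deg[which.max(oh$weights)] - 30), 5)
  # plain angle vectors work too; delta input -> single bin
  oh2 <- orientation_histogram(rep(32, 100))
  expect_equal(sum(oh2$weights > 0), 1)
  expect_equal(which(oh2$weights > 0), 7)  # [30, 35)
  # uniform angles: no bin dominates at n = 10^4
  set.seed(5)
  oh3 <- orientation_histogram(runif(1e4, 0, 180))
  expect_lte(max(oh3$weights), 2 / 36)
  expect_error(orientation_histogram(of, min_coherence = 2), "min_coherence")
})

test_that("axis alignment cyclically shifts bins and records the offset", {
  w <- c(rep(0, 17), 1, rep(0, 18))
  oh <- orientation_histogram(rep(87.5, 10))  # mass in bin 18
  expect_equal(oh$weights, w)
  ali <- align_to_axis(oh, 90)
  expect_equal(ali$axis_offset_deg, 90)
  expect_equal(which(ali$weights > 0), 36)   # shifted by 18 bins
  expect_equal(align_to_axis(oh, 0)$weights, oh$weights)
})

test_that("circular order parameters behave at the closed-form cases", {
  expect_equal(circular_order(rep(42, 7))$R, 1)
  expect_equal(circular_order(rep(42, 7))$mean_deg, 42)
  # equal mass at 0 and 90: doubled angles antipodal -> R exactly 0
  expect_equal(circular_order(c(0, 90))$R, 0, tolerance = 1e-12)
  set.seed(6)
  expect_lt(circular_order(runif(2e4, 0, 180))$R, 0.03)
  expect_error(circular_order(numeric(0)), "empty")
})

test_that("fiber-image recovery: mean within 2 deg, R monotone in kappa", {
  Rs <- c()
  for (kap in c(2, 8, 32)) {
    fi <- make_fiber_image(120, mu_deg = 50, kappa = kap, size = 160,
                           noise_sd = 0.05, seed = 21)
    oh <- orientation_histogram(structure_tensor_orientation(fi$image))
    co <- circular_order(oh)
    if (kap >= 8) {
      d <- min(abs(co$mean_deg - 50), 180 - abs(co$mean_deg - 50))
      expect_lt(d, 2)
    }
    Rs <- c(Rs, co$R)
  }
  expect_true(all(diff(Rs) > 0))
})
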