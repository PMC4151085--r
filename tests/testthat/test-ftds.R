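test_that("uniform Ds and Fj give a fully symmetric layer", {
  g <- hex_grid(4, 10)
  layer <- solve_ftds_layer(g, 1, 0.5)
  expect_lt(max(layer$asymmetry), 1e-10)
  # every junction balanced: forward equals reverse occupancy
  H_rev <- matrix(layer$H[g$partner], g$n_cells, 6)
  expect_equal(layer$H, H_rev, tolerance = 1e-10)
})

test_that("equilibrium matches brute-force kinetics on a 1x3 grid", {
  g <- hex_grid(1, 3)
  ds <- c(1.5, 0.8, 0.1)
  fj <- c(0.1, 0.8, 1.5)
  layer <- solve_ftds_layer(g, make_gradient("custom", 3, values = ds),
                            make_gradient("custom", 3, values = fj))
  H_oracle <- oracle_ftds(g, ds[g$col], fj[g$col], rep(1, 3))
  expect_lt(max(abs(layer$H - H_oracle)), 1e-8)
})

test_that("a distally decreasing Ds gradient anchors Ft proximally", {
  g <- hex_grid(4, 12)
  layer <- solve_ftds_layer(g, make_gradient("linear", 12),
                            make_gradient("linear", 12, high = 0.1, low = 1.5))
  mid <- which(g$col %in% 4:9)
  # bound Ft higher on the proximal (edge 4) than the distal (edge 1) side
  expect_true(all(layer$H[mid, 4] > layer$H[mid, 1]))
  # so the bias vector (plus-end direction) points distally
  expect_true(all(layer$bias[mid, 1] > 0))
})

test_that("wildtype neighbors accumulate Ft on the clone-facing junction", {
  g <- hex_grid(6, 12)
  ft <- rep(1, g$n_cells)
  clone <- which(g$row %in% 3:4 & g$col %in% 6:7)
  ft[clone] <- 0
  layer <- solve_ftds_layer(g, 1, 0.5, ft_total = ft)
  # clone cells bind no Ft at all
  expect_equal(max(layer$H[clone, ]), 0)
  for (i in setdiff(which(g$col %in% 5:8), clone)) {
    facing <- which(g$nbr[i, ] %in% clone)
    if (length(facing) == 0) next
    expect_in(which.max(layer$H[i, ]), facing)
  }
})

test_that("mass conservation holds at the fixed point", {
  g <- hex_grid(3, 8)
  layer <- solve_ftds_layer(g, make_gradient("step", 8, step_col = 4), 0.5)
  expect_equal(layer$ft_free + rowSums(layer$H), layer$ft_tot,
               tolerance = 1e-9)
  ds_bound <- rowSums(matrix(layer$H[g$partner], g$n_cells, 6))
  expect_equal(layer$ds_free + ds_bound, layer$ds_total, tolerance = 1e-9)
  expect_true(all(layer$H >= 0))
})

test_that("propagation past a steep Ds step is limited to two columns", {
  g <- hex_grid(6, 30)
  layer <- solve_ftds_layer(g, make_gradient("step", 30, step_col = 8), 0.5)
  expect_lte(measure_propagation_columns(layer, 8), 2)
  # no step, no propagation
  layer_u <- solve_ftds_layer(g, 1, 0.5)
  expect_equal(measure_propagation_columns(layer_u, 8), 0L)
})

test_that("propagation count matches hand enumeration on a 1x4 toy layer", {
  g <- hex_grid(1, 4)
  layer <- solve_ftds_layer(g, 1, 0.5)
  # hand-set occupancies: column 3 asymmetric, others balanced
  layer$H[] <- 0.2
  layer$H[3, 1] <- 0.5
  layer$bias <- cbind(-layer$H %*% g$normal[, 1], -layer$H %*% g$normal[, 2])
  layer$asymmetry <- sqrt(rowSums(layer$bias^2))
  # column means: (0, 0, 0.3, 0); threshold 0.05 * 0.3; step at column 2:
  # column 3 above, column 4 below -> exactly 1
  expect_equal(measure_propagation_columns(layer, 2, threshold_frac = 0.05), 1L)
})

test_that("mt bias modes obey their contracts", {
  g <- hex_grid(3, 8)
  layer <- solve_ftds_layer(g, 1, 0.5)   # zero bias everywhere
  f <- mt_bias_from_ftds(layer, "coupled")
  expect_equal(f$m, matrix(1 / 6, g$n_cells, 6), tolerance = 1e-12)

  f2 <- mt_bias_from_ftds(layer, "oriented_unbiased")
  expect_equal(f2$m[, 1], rep(0.5, g$n_cells))
  expect_equal(f2$m[, 4], rep(0.5, g$n_cells))
  expect_equal(rowSums(f2$m), rep(1, g$n_cells))

  # strong proximal anchoring -> delivery maximal on the distal edge
  layer$bias <- cbind(rep(1, g$n_cells), rep(0, g$n_cells))
  f3 <- mt_bias_from_ftds(layer, "coupled")
  expect_equal(unname(apply(f3$m, 1, which.max)), rep(1L, g$n_cells))
  expect_equal(rowSums(f3$m), rep(1, g$n_cells), tolerance = 1e-12)

  expect_error(mt_bias_from_ftds(layer, "imposed"), "m_imposed")
  bad <- matrix(0, g$n_cells, 6)
  expect_error(mt_bias_from_ftds(layer, "imposed", m_imposed = bad),
               "normalizable")
})
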