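test_that("a symmetric wildtype field stays exactly unpolarized", {
  g <- hex_grid(4, 6)
  sim <- simulate_core(g, NULL, t_end = 5, save_dt = 1)
  expect_lt(max(sim$magnitude), 1e-12)
})

test_that("per-cell totals are conserved along trajectories", {
  g <- hex_grid(3, 8)
  sim <- pcp_pipeline(g, make_gradient("linear", 8), t_end = 30)
  tot <- sim$totals
  for (sp in c("dsh", "fz", "vang", "pk")) {
    expect_lt(max(abs(tot[[sp]] - 1)), 1e-6)
  }
  # no negative concentrations in the final state
  expect_gte(min(wingpol:::core_pack(sim$state)), -1e-10)
})

test_that("fz-null cells never form Dsh-Fz complexes", {
  g <- hex_grid(3, 8)
  cl <- clone_block(g, 2, 4:5, "fz")
  sim <- pcp_pipeline(g, make_gradient("linear", 8), clones = list(cl),
                      t_end = 20)
  expect_equal(max(sim$state$DF[cl$cells, ]), 0)
  expect_equal(max(sim$state$BD[cl$cells, ]), 0)
  expect_equal(max(sim$state$Fz[cl$cells, ]), 0)
})

test_that("no Ft anywhere means uniform delivery and no polarity", {
  g <- hex_grid(3, 8)
  layer <- solve_ftds_layer(g, make_gradient("linear", 8), 0.5,
                            ft_total = rep(0, g$n_cells))
  bias <- mt_bias_from_ftds(layer, "coupled")
  expect_equal(bias$m, matrix(1 / 6, g$n_cells, 6), tolerance = 1e-12)
  sim <- simulate_core(g, bias, t_end = 5)
  expect_lt(max(sim$magnitude), 1e-12)
})

test_that("mirroring the gradients mirrors the polarity field", {
  g <- hex_grid(1, 12)
  ds <- make_gradient("linear", 12)
  ds_rev <- make_gradient("custom", 12, values = rev(ds$values))
  s1 <- pcp_pipeline(g, ds, t_end = 60, save_dt = 10)
  s2 <- pcp_pipeline(g, ds_rev, t_end = 60, save_dt = 10)
  n_t <- length(s1$times)
  # cell i of run 1 corresponds to cell (13 - i) of run 2 with px negated
  expect_equal(s1$P[n_t, , 1], -s2$P[n_t, 12:1, 1], tolerance = 1e-8)
  expect_equal(s1$P[n_t, , 2], s2$P[n_t, 12:1, 2], tolerance = 1e-8)
})

test_that("halving the integrator step barely changes the solution", {
  g <- hex_grid(2, 8)
  s1 <- pcp_pipeline(g, make_gradient("linear", 8), t_end = 40)
  s2 <- pcp_pipeline(g, make_gradient("linear", 8), t_end = 40, dt = 0.005)
  n1 <- length(s1$times); n2 <- length(s2$times)
  m1 <- mean(s1$magnitude[n1, ]); m2 <- mean(s2$magnitude[n2, ])
  expect_lt(abs(m1 - m2) / m2, 0.001)
})

test_that("polarity readout equals the hand-built vector sum", {
  g <- hex_grid(1, 1)
  s <- wingpol:::core_initial_state(1, 1, 1, 1, 1)
  # all membrane Dsh on the distal (+x) edge
  s$Dm[1, 1] <- 0.3
  s$DF[1, 1] <- 0.2
  sim <- structure(list(times = 0, P = array(wingpol:::polarity_vectors(s, g),
                                             c(1, 1, 2)),
                        magnitude = matrix(0.5, 1, 1), state = s, grid = g,
                        steady = TRUE),
                   class = "pcp_sim")
  ro <- render_polarity(sim)
  expect_equal(ro$cells$magnitude, 0.5)
  expect_equal(ro$cells$angle_deg, 0)
  # arbitrary state: vector sum matches direct summation over edges
  s$Dm[1, ] <- c(0.1, 0.05, 0, 0.2, 0.1, 0)
  P <- wingpol:::polarity_vectors(s, g)
  md <- s$Dm + s$DF + s$BD
  expect_equal(unname(P[1, 1]), sum(md * g$normal[, 1]))
  expect_equal(unname(P[1, 2]), sum(md * g$normal[, 2]))
})

test_that("kinetics summaries expose rise times per column", {
  g <- hex_grid(2, 10)
  sim <- pcp_pipeline(g, make_gradient("linear", 10), t_end = 80,
                      save_dt = 2)
  kin <- suppressWarnings(polarization_kinetics(sim, c(2, 8)))
  expect_equal(dim(kin$mean_P), c(length(sim$times), 2))
  expect_true(all(kin$t90 > 0 & kin$t90 <= 80))
})

test_that("raising the transport rate does not weaken polarization", {
  g <- hex_grid(1, 10)
  ds <- make_gradient("linear", 10)
  m_lo <- pcp_pipeline(g, ds, core_par = core_params(k_T = 0.5),
                       t_end = 250, save_dt = 25)
  m_hi <- pcp_pipeline(g, ds, core_par = core_params(k_T = 1),
                       t_end = 250, save_dt = 25)
  p_lo <- mean(m_lo$magnitude[length(m_lo$times), ])
  p_hi <- mean(m_hi$magnitude[length(m_hi$times), ])
  expect_gte(p_hi, p_lo * 0.99)
})
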