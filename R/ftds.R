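## Fat-Dachsous heterodimer layer.
##
## Ft and Ds are atypical cadherins binding in trans across junctions; the
## Golgi kinase Four-jointed (Fj) phosphorylates both, increasing Ft's and
## decreasing Ds's affinity. Opposing tissue gradients of Ds and Fj therefore
## convert into a subcellular asymmetry of bound Ft-Ds heterodimers. The
## layer is quasi-static: gradients are fixed inputs and the binding
## equilibrium is solved before the core-PCP dynamics run.

#' Parameters of the Ft-Ds binding layer
#'
#' Nondimensional mass-action constants. Forward binding at a junction
#' between cell i (contributing Ft) and neighbor j (contributing Ds) runs at
#' `k_on * aF(Fj_i) * aD(Fj_j) * Ft_free_i * Ds_free_j` with
#' `aF(F) = 1 + alpha_F * F` (Fj activates Ft) and
#' `aD(F) = 1 / (1 + alpha_D * F)` (Fj inhibits Ds); unbinding at `k_off * H`.
#'
#' @param k_on,k_off binding/unbinding rates (> 0).
#' @param alpha_F,alpha_D Fj modulation strengths (>= 0).
#' @param ft_total default per-cell total Ft (uniform).
#' @param tol convergence tolerance on `max |dH/dt|`.
#' @param max_iter iteration cap.
#' @param dt pseudo-time relaxation step of the fixed-point solver.
#' @return list of parameters.
#' @export
ftds_params <- function(k_on = 1, k_off = 1, alpha_F = 1, alpha_D = 1,
                        ft_total = 1, tol = 1e-11, max_iter = 100000,
                        dt = 0.05) {
  if (k_on <= 0 || k_off <= 0) stop_param("rate parameters must be > 0")
  if (alpha_F < 0 || alpha_D < 0) stop_param("alpha_F, alpha_D must be >= 0")
  list(k_on = k_on, k_off = k_off, alpha_F = alpha_F, alpha_D = alpha_D,
       ft_total = ft_total, tol = tol, max_iter = max_iter, dt = dt)
}

#' Solve the Ft-Ds heterodimer binding equilibrium
#'
#' Relaxes the mass-action binding kinetics
#' `dH/dt = k_on aF aD Ft_free Ds_free - k_off H` in pseudo-time until the
#' maximal rate of change falls below `params$tol` (quasi-static layer).
#' `H[i, e]` is the concentration of trans-dimers whose Ft belongs to cell
#' `i` at edge `e` (their Ds belongs to the neighbor across that edge). Free
#' pools are well mixed per cell and tied to the totals by conservation.
#'
#' Boundary handling: with `boundary = "mirror"` (default) an outer edge
#' binds against a virtual mirror image of its own cell, so a uniform tissue
#' is exactly symmetric everywhere; with `"open"` outer edges do not bind.
#'
#' @param grid a [hex_grid()].
#' @param ds Ds gradient ([make_gradient()]), scalar or per-cell vector.
#' @param fj Fj gradient, scalar or per-cell vector.
#' @param params from [ftds_params()].
#' @param ft_total optional per-cell Ft totals (overrides `params$ft_total`;
#'   used by *ft* clones).
#' @param boundary `"mirror"` or `"open"`.
#' @return object of class `ftds_layer`: list with `H` (`n_cells x 6` bound
#'   Ft per edge), `ft_free`, `ds_free`, `ds_total`, `ft_tot`, `fj`, `bias`
#'   (`n_cells x 2` matrix of per-cell bias vectors
#'   `b_i = -sum_e H[i,e] * n_e`, pointing away from the Ft-rich, anchoring
#'   side, i.e. toward microtubule plus ends), `asymmetry` (`|b_i|`),
#'   `iterations`, `residual`, and the `grid`.
#' @examples
#' g <- hex_grid(3, 8)
#' layer <- solve_ftds_layer(g, make_gradient("linear", 8), 0.5)
#' @export
solve_ftds_layer <- function(grid, ds, fj = 0.5, params = ftds_params(),
                             ft_total = NULL,
                             boundary = c("mirror", "open")) {
  boundary <- match.arg(boundary)
  n <- grid$n_cells
  ds_tot <- per_cell_levels(grid, ds, "Ds gradient")
  fj_lev <- per_cell_levels(grid, fj, "Fj gradient")
  ft_tot <- if (is.null(ft_total)) rep(params$ft_total, n)
            else per_cell_levels(grid, ft_total, "Ft totals")
  if (any(ft_tot < 0)) stop_param("Ft totals must be >= 0")

  aF <- 1 + params$alpha_F * fj_lev
  aD <- 1 / (1 + params$alpha_D * fj_lev)
  part <- grid$partner
  open_bd <- boundary == "open"
  bd_mask <- matrix(FALSE, n, 6)
  for (e in 1:6) bd_mask[, e] <- is.na(grid$nbr[, e])

  ## cell index of the Ds-contributing partner at each junction (self at
  ## mirror boundary); aD evaluated at that cell's Fj level
  part_cell <- matrix(((part - 1L) %% n) + 1L, n, 6)
  aD_across <- matrix(aD[part_cell], n, 6)

  H <- matrix(0, n, 6)
  dt <- params$dt
  res <- Inf
  it <- 0L
  while (it < params$max_iter) {
    it <- it + 1L
    ft_free <- pmax(ft_tot - rowSums(H), 0)
    ## Ds of cell i bound = dimers whose Ds side is i = H at apposed edges
    ds_bound <- rowSums(matrix(H[part], n, 6))
    ds_free <- pmax(ds_tot - ds_bound, 0)
    ds_free_across <- matrix(ds_free[part_cell], n, 6)
    rate <- params$k_on * aF * aD_across * ft_free * ds_free_across -
      params$k_off * H
    if (open_bd) rate[bd_mask] <- -params$k_off * H[bd_mask]
    H <- pmax(H + dt * rate, 0)
    res <- max(abs(rate))
    if (res < params$tol) break
  }
  if (res >= params$tol)
    stop(sprintf("Ft-Ds layer did not converge after %d iterations (residual %.3g)",
                 it, res), call. = FALSE)

  ft_free <- pmax(ft_tot - rowSums(H), 0)
  ds_bound <- rowSums(matrix(H[part], n, 6))
  ds_free <- pmax(ds_tot - ds_bound, 0)
  bias <- cbind(-H %*% grid$normal[, 1], -H %*% grid$normal[, 2])
  colnames(bias) <- c("bx", "by")
  structure(
    list(H = H, ft_free = ft_free, ds_free = ds_free,
         ds_total = ds_tot, ft_tot = ft_tot, fj = fj_lev,
         bias = bias, asymmetry = sqrt(rowSums(bias^2)),
         iterations = it, residual = res, boundary = boundary, grid = grid),
    class = "ftds_layer")
}

#' @export
print.ftds_layer <- function(x, ...) {
  cat(sprintf("ftds_layer: %d cells, %d iterations, residual %.2g\n",
              x$grid$n_cells, x$iterations, x$residual))
  cat(sprintf("  mean |Ft-Ds asymmetry| = %.4g\n", mean(x$asymmetry)))
  invisible(x)
}

#' Microtubule delivery-bias field from the Ft-Ds layer
#'
#' Converts junctional bound-Ft weights into per-cell, per-edge microtubule
#' delivery weights `m[i, e]` (the fraction of directed vesicle traffic
#' arriving at edge `e`; rows sum to 1). Minus ends anchor at Ft-rich edges,
#' so plus ends -- and delivery -- point away from them: the per-cell bias
#' vector is `b_i = -sum_e w(i,e) n_e` with `w = H` (bound Ft).
#'
#' @param layer a solved [solve_ftds_layer()].
#' @param mode `"coupled"` (delivery `m propto eps + max(b_i . n_e, 0)^q`),
#'   `"random"` (uniform 1/6), `"oriented_unbiased"` (1/2 on each of the two
#'   P-D edges: microtubules P-D oriented but without plus-end bias), or
#'   `"imposed"` (user weights). May be a single string or a per-cell
#'   character vector to enforce different microtubule architectures in
#'   different regions.
#' @param q sharpness exponent of the coupled mapping (default 1).
#' @param eps strictly positive floor guaranteeing positive weights (and
#'   uniform delivery when the bias vanishes); default 0.2.
#' @param m_imposed `n_cells x 6` matrix of weights for `"imposed"` cells.
#' @return object of class `mt_bias_field`: list with `m` (`n_cells x 6`,
#'   rows sum to 1), `b` (bias vectors), `mode` (per-cell), `grid`.
#' @examples
#' g <- hex_grid(3, 8)
#' layer <- solve_ftds_layer(g, make_gradient("linear", 8))
#' field <- mt_bias_from_ftds(layer)
#' @export
mt_bias_from_ftds <- function(layer, mode = "coupled", q = 1, eps = 0.2,
                              m_imposed = NULL) {
  grid <- layer$grid
  n <- grid$n_cells
  if (eps <= 0) stop_param("eps must be > 0")
  modes <- c("coupled", "random", "oriented_unbiased", "imposed")
  if (length(mode) == 1L) mode <- rep(mode, n)
  if (length(mode) != n) stop_param("mode must be length 1 or n_cells")
  if (!all(mode %in% modes))
    stop_param("unknown mt mode; use one of %s", paste(modes, collapse = ", "))

  b <- layer$bias
  m <- matrix(1 / 6, n, 6)
  cp <- mode == "coupled"
  if (any(cp)) {
    proj <- b %*% t(grid$normal)       # b_i . n_e
    w <- eps + pmax(proj, 0)^q
    m[cp, ] <- w[cp, , drop = FALSE] / rowSums(w[cp, , drop = FALSE])
  }
  ou <- mode == "oriented_unbiased"
  if (any(ou)) {
    mo <- matrix(0, sum(ou), 6)
    mo[, 1] <- 0.5  # +x (distal)
    mo[, 4] <- 0.5  # -x (proximal)
    m[ou, ] <- mo
  }
  im <- mode == "imposed"
  if (any(im)) {
    if (is.null(m_imposed)) stop_param("mode 'imposed' needs m_imposed")
    mi <- m_imposed[im, , drop = FALSE]
    if (any(mi < 0) || any(rowSums(mi) <= 0))
      stop_param("imposed weights not normalizable")
    m[im, ] <- mi / rowSums(mi)
  }
  structure(list(m = m, b = b, mode = mode, grid = grid),
            class = "mt_bias_field")
}

#' @export
print.mt_bias_field <- function(x, ...) {
  cat(sprintf("mt_bias_field: %d cells, modes: %s\n", nrow(x$m),
              paste(names(table(x$mode)), collapse = ", ")))
  invisible(x)
}

#' Count columns reached by Ft-Ds polarity beyond a gradient step
#'
#' Propagation of the Ft-Ds asymmetry into a flat region is weak: with a
#' steep proximal Ds step and flat Ds/Fj beyond it, only the first column or
#' two distal to the step retain appreciable junctional asymmetry. Counts
#' consecutive columns distal to `step_col` whose column-mean asymmetry
#' `A_i = |sum_e H[i,e] n_e|` exceeds `threshold_frac` times the maximum
#' column mean.
#'
#' @param layer a solved [solve_ftds_layer()].
#' @param step_col index of the last high-Ds column.
#' @param threshold_frac fraction of the maximum column-mean asymmetry
#'   (default 0.05).
#' @return integer count of above-threshold columns distal to the step.
#' @export
measure_propagation_columns <- function(layer, step_col,
                                        threshold_frac = 0.05) {
  grid <- layer$grid
  if (step_col < 1 || step_col > grid$n_cols)
    stop_param("step_col outside grid")
  colA <- column_means(grid, layer$asymmetry)
  if (max(colA) < 1e-12) return(0L)  # no asymmetry anywhere (uniform input)
  thr <- threshold_frac * max(colA)
  count <- 0L
  for (cc in seq(step_col + 1L, length.out = grid$n_cols - step_col)) {
    if (colA[cc] > thr) count <- count + 1L else break
  }
  count
}
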