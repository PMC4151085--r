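## Core planar-cell-polarity feedback model.
##
## Species per cell: cytoplasmic Dsh, Pk and Vang pools; per edge: free
## membrane Fz and Vang, free membrane Dsh, Dsh-Fz complexes, Pk-Vang
## complexes; per junction: intercellular Fz-Vang bridges, with and without
## bound Dsh. Feedback topology: directed (microtubule-biased) Dsh transport
## seeds Dsh-Fz on one membrane; Dsh-Fz stabilizes Fz-Vang bridges and
## recruits Vang to the apposed membrane of the neighbor; Pk-Vang on a
## membrane inhibits local Dsh-Fz formation. Lateral diffusion moves
## membrane species between adjacent edges of the same cell. No synthesis
## or degradation: per-cell totals are conserved.

#' Clone specification
#'
#' Marks a set of cells as null for one gene product: the corresponding
#' per-cell total is set to zero in those cells. *ft* and *ds* clones act on
#' the Ft-Ds layer; *fz*, *dsh*, *vang* and *pk* clones act on the core layer.
#'
#' @param cells integer cell indices.
#' @param species one of `"fz"`, `"dsh"`, `"ft"`, `"ds"`, `"vang"`, `"pk"`.
#' @return object of class `clone_spec`.
#' @export
clone_spec <- function(cells, species) {
  species <- match.arg(species, c("fz", "dsh", "ft", "ds", "vang", "pk"))
  if (length(cells) == 0) stop_param("clone with no cells")
  structure(list(cells = as.integer(cells), species = species),
            class = "clone_spec")
}

#' Rectangular clone helper
#' @param grid a [hex_grid()].
#' @param rows,cols row/column ranges of the clone.
#' @param species gene product set to zero, see [clone_spec()].
#' @return a [clone_spec()].
#' @export
clone_block <- function(grid, rows, cols, species) {
  cells <- which(grid$row %in% rows & grid$col %in% cols)
  clone_spec(cells, species)
}

#' Core-model rate constants
#'
#' Nondimensional rate constants of the core feedback network.
#'
#' * `k_T` / `k_ret`: directed Dsh membrane delivery (split over edges by
#'   the microtubule weights `m`) and return to the cytoplasm.
#' * `k1` / `k1_off`: Dsh-Fz association and dissociation. Association is
#'   suppressed by local Pk-Vang with strength `beta` (cooperativity `h`);
#'   dissociation is raised up to `(1 + phi)`-fold when the apposed membrane
#'   is itself Dsh-Fz-rich (a head-to-head pair has no trans Vang partner),
#'   which lets polarity fronts melt misoriented domains.
#' * `k2` / `k2_off`: intercellular Fz-Vang bridge formation and
#'   dissociation; dissociation is reduced by the factor `s_D` when the Fz
#'   side carries Dsh (stabilization), and shares the `phi` frustration
#'   term.
#' * `k3` / `k3_off`: Vang membrane recruitment and return. Recruitment is
#'   gated by the presence of any apposed Fz (half-point set by `delta_g`)
#'   and optionally enhanced up to `(1 + e_max)`-fold by apposed Dsh-Fz
#'   (half-point `1/delta`; `e_max = 0` by default).
#' * `k4` / `k4_off`: Pk-Vang assembly from membrane Vang and cytoplasmic
#'   Pk, and disassembly. Assembly is suppressed by local Dsh-Fz (strength
#'   `gamma`, the reciprocal arm of the membrane toggle) and enhanced up to
#'   `(1 + e_pv)`-fold by apposed Dsh-Fz; disassembly is slowed (down to the
#'   floor `eps_s`) by trans binding to any apposed Fz (half-point
#'   `1/delta_s`), so Pk-Vang persists opposite Fz-presenting cells but
#'   decays facing fz-null tissue.
#' * `D_m`: lateral hop rate of free membrane species (Fz, Vang, Dsh)
#'   between adjacent edges; `D_c`: the (slower) hop rate of Dsh-Fz and
#'   Pk-Vang clusters; bridges do not move.
#' * `h`: cooperativity exponent shared by the nonlinear terms. `h = 1`
#'   (plain first-order inhibition and enhancement) amplifies too weakly to
#'   polarize; the default `h = 2` gives the bistable membrane toggle the
#'   feedback requires.
#'
#' @param k_T,k_ret,k1,k1_off,beta,k2,k2_off,s_D,k3,k3_off,delta,k4,k4_off,gamma,D_m,D_c,phi,h,e_max,e_pv,delta_s,eps_s,delta_g
#'   rate constants, see Details.
#' @param fz_total,vang_total,dsh_total,pk_total default per-cell totals.
#' @return list of parameters.
#' @export
core_params <- function(k_T = 1, k_ret = 0.09,
                        k1 = 2, k1_off = 0.08, beta = 60,
                        k2 = 1, k2_off = 0.1, s_D = 0.01,
                        k3 = 1, k3_off = 6, delta = 10,
                        k4 = 6.5, k4_off = 10, gamma = 30, D_m = 0.2,
                        D_c = 0.05, phi = 10,
                        h = 2, e_max = 0, e_pv = 200,
                        delta_s = 15, eps_s = 0.1, delta_g = 15,
                        fz_total = 1, vang_total = 1,
                        dsh_total = 1, pk_total = 1) {
  as.list(environment())
}

## fixed parameter order shared with src/core_rhs.cpp
core_par_vec <- function(p) {
  as.numeric(unlist(p[c("k_T", "k_ret", "k1", "k1_off", "beta", "k2",
                        "k2_off", "s_D", "k3", "k3_off", "delta", "k4",
                        "k4_off", "gamma", "D_m", "D_c", "phi", "h",
                        "e_max", "e_pv", "delta_s", "eps_s", "delta_g")]))
}

## ---- state packing ----------------------------------------------------
## y = [DshC, PkC, VangC | Fz, Vm, Dm, DF, PV, B0, BD] (cell blocks, then
## n x 6 edge blocks column-major)

core_unpack <- function(y, n) {
  i <- 0L
  take_cell <- function() { v <- y[(i + 1L):(i + n)]; i <<- i + n; v }
  take_edge <- function() { m <- matrix(y[(i + 1L):(i + 6L * n)], n, 6); i <<- i + 6L * n; m }
  list(DshC = take_cell(), PkC = take_cell(), VangC = take_cell(),
       Fz = take_edge(), Vm = take_edge(), Dm = take_edge(),
       DF = take_edge(), PV = take_edge(), B0 = take_edge(),
       BD = take_edge())
}

core_pack <- function(s) {
  c(s$DshC, s$PkC, s$VangC,
    as.numeric(s$Fz), as.numeric(s$Vm), as.numeric(s$Dm),
    as.numeric(s$DF), as.numeric(s$PV), as.numeric(s$B0),
    as.numeric(s$BD))
}

## RHS of the core model. ctx carries precomputed grid indices & parameters.
core_rhs <- function(y, ctx) {
  n <- ctx$n
  p <- ctx$p
  s <- core_unpack(y, n)
  part <- ctx$part
  eL <- ctx$eL; eR <- ctx$eR

  across <- function(X) matrix(X[part], n, 6)
  lap <- function(X) X[, eL, drop = FALSE] + X[, eR, drop = FALSE] - 2 * X

  inh <- 1 / (1 + (p$beta * s$PV)^p$h)

  r_T <- p$k_T * ctx$m * s$DshC          # DshC -> Dm (directed transport)
  r_ret <- p$k_ret * s$Dm                # Dm -> DshC
  r_DF_on <- p$k1 * s$Dm * s$Fz * inh    # Dm + Fz -> DF
  ## Dsh-Fz facing apposed Dsh-Fz has no trans Vang partner and is
  ## destabilized (strength phi): head-to-head polarity walls melt from
  ## whichever side lacks support, so orientation propagates as a front
  u_ff <- (p$delta * matrix((s$DF + s$BD)[part], n, 6))^p$h
  r_DF_off <- p$k1_off * s$DF * (1 + p$phi * u_ff / (1 + u_ff))
  Vm_ac <- across(s$Vm)
  r_B0_on <- p$k2 * s$Fz * Vm_ac         # Fz + Vang(across) -> B0
  r_B0_off <- p$k2_off * s$B0
  ## bridge engagement of Dsh-Fz is blocked at frustrated junctions
  ## (apposed membrane itself Dsh-Fz-rich): no trans partner to bind
  r_BD_on1 <- p$k2 * s$DF * Vm_ac / (1 + u_ff)
  ## stabilized dissociation; the phi frustration term also unlocks
  ## bridges at head-to-head junctions
  r_BD_off1 <- p$s_D * p$k2_off * s$BD * (1 + p$phi * u_ff / (1 + u_ff))
  r_BD_on2 <- p$k1 * s$Dm * s$B0 * inh   # Dm + B0 -> BD
  r_BD_off2 <- p$k1_off * s$BD
  ## Vang recruitment and Pk-Vang assembly are enhanced across the junction
  ## by apposed Dsh-Fz (active Fz), cooperatively (exponent h), saturating
  ## at fold-changes 1 + e_max and 1 + e_pv respectively: active Fz pulls
  ## Vang opposite itself and locks it there as Pk-Vang, enforcing parallel
  ## alignment of neighbors.
  u <- (p$delta * across(s$DF + s$BD))^p$h
  sat <- u / (1 + u)
  ## recruitment additionally gated by the presence of ANY apposed Fz
  ## (free or complexed, strength delta_g, saturating): Vang only loads
  ## onto membranes that face a Fz-presenting cell. dsh-null tissue still
  ## presents free Fz (gate stays open, neighbors keep their Vang);
  ## fz-null tissue presents none (gate shut, neighbor Vang unloads and
  ## polarity flips toward the clone).
  S_tot <- across(s$Fz + s$DF + s$B0 + s$BD)
  u_g <- (p$delta_g * S_tot)^p$h
  gate <- u_g / (1 + u_g)
  r_V_on <- p$k3 * s$VangC * (1 + p$e_max * sat) * gate
  r_V_off <- p$k3_off * s$Vm
  ## reciprocal intramembrane antagonism: local Dsh-Fz suppresses Pk-Vang
  ## assembly on the same membrane (mirror of the beta term). Assembly is
  ## promoted by this membrane's trans-engaged Vang (the Vang side of the
  ## partner's bridges, strength e_pv): Vang held by apposed Fz recruits
  ## Pk. Bare bridges carry the signal in dsh-null tissue; fz-null tissue
  ## forms none.
  inh_pv <- 1 / (1 + (p$gamma * (s$DF + s$BD))^p$h)
  r_PV_on <- p$k4 * s$PkC * s$Vm * inh_pv * (1 + p$e_pv * sat)
  ## Pk-Vang clusters are stabilized by trans binding to ANY apposed Fz
  ## (free or complexed, strength delta_s, saturating to a dissociation
  ## floor eps_s): nearly uniform in wildtype tissue, absent facing fz-null
  ## cells -- there Pk-Vang decays, Dsh-Fz nucleates, and the neighbors
  ## repolarize toward the clone (domineering non-autonomy); dsh-null cells
  ## still present free Fz, so their neighbors hold polarity.
  u_s <- (p$delta_s * S_tot)^p$h
  r_PV_off <- p$k4_off * s$PV * (p$eps_s + (1 - p$eps_s) / (1 + u_s))

  ## Vang consumed/released on THIS membrane by the partner's bridges
  cap <- across(r_B0_on + r_BD_on1)
  rel <- across(r_B0_off + r_BD_off1)

  d <- list(
    DshC = -rowSums(r_T) + rowSums(r_ret),
    PkC  = -rowSums(r_PV_on) + rowSums(r_PV_off),
    VangC = -rowSums(r_V_on) + rowSums(r_V_off),
    Fz = -r_DF_on + r_DF_off - r_B0_on + r_B0_off + p$D_m * lap(s$Fz),
    Vm = r_V_on - r_V_off - r_PV_on + r_PV_off - cap + rel +
      p$D_m * lap(s$Vm),
    Dm = r_T - r_ret - r_DF_on + r_DF_off - r_BD_on2 + r_BD_off2 +
      p$D_m * lap(s$Dm),
    DF = r_DF_on - r_DF_off - r_BD_on1 + r_BD_off1 + p$D_c * lap(s$DF),
    PV = r_PV_on - r_PV_off + p$D_c * lap(s$PV),
    B0 = r_B0_on - r_B0_off - r_BD_on2 + r_BD_off2,
    BD = r_BD_on1 - r_BD_off1 + r_BD_on2 - r_BD_off2
  )
  core_pack(d)
}

core_initial_state <- function(n, fz_tot, vang_tot, dsh_tot, pk_tot) {
  zed <- matrix(0, n, 6)
  ## membrane proteins start uniform over edges; Dsh and Pk cytoplasmic
  list(DshC = dsh_tot, PkC = pk_tot, VangC = rep(0, n),
       Fz = matrix(fz_tot / 6, n, 6), Vm = matrix(vang_tot / 6, n, 6),
       Dm = zed, DF = zed, PV = zed, B0 = zed, BD = zed)
}

## membrane Dsh (free + complexed) per cell x edge
membrane_dsh <- function(s) s$Dm + s$DF + s$BD

polarity_vectors <- function(s, grid) {
  md <- membrane_dsh(s)
  cbind(px = as.numeric(md %*% grid$normal[, 1]),
        py = as.numeric(md %*% grid$normal[, 2]))
}

#' Simulate the core PCP reaction network
#'
#' Integrates the core feedback model with fixed-step classical Runge-Kutta,
#' starting from a symmetric state (all Fz uniform on the membrane, Dsh, Pk
#' and Vang cytoplasmic), until `t_end` or until steady state
#' (`max |dy/dt| < tol_ss`), whichever comes first. The per-cell polarity
#' vector `P_i = sum_e membrane-Dsh(i, e) * n_e` is recorded every
#' `save_dt` time units.
#'
#' @param grid a [hex_grid()].
#' @param bias a [mt_bias_from_ftds()] field (or `NULL` for uniform
#'   delivery).
#' @param clones list of [clone_spec()] for core species (`fz`, `dsh`,
#'   `vang`, `pk`); `ft`/`ds` clones must be applied to the layer instead.
#' @param params from [core_params()].
#' @param t_end integration horizon (nondimensional time).
#' @param dt integrator step.
#' @param save_dt interval between saved polarity snapshots.
#' @param tol_ss steady-state threshold on `max |dy/dt|`.
#' @param init_noise multiplicative noise amplitude on the initial membrane
#'   Fz (default 0 = deterministic); requires `seed`.
#' @param seed RNG seed used only when `init_noise > 0`.
#' @param engine `"compiled"` (C++ right-hand side, default) or
#'   `"reference"` (the pure-R implementation; same equations, kept as a
#'   cross-check).
#' @return object of class `pcp_sim`: list with `times`, `P` (array
#'   `n_times x n_cells x 2`), `magnitude` (`n_times x n_cells`),
#'   `state` (final state list), `steady` (logical), `max_dydt`,
#'   `totals` (per-cell conserved totals), `grid`, `bias`, `params`.
#' @examples
#' g <- hex_grid(2, 6)
#' layer <- solve_ftds_layer(g, make_gradient("linear", 6))
#' sim <- simulate_core(g, mt_bias_from_ftds(layer), t_end = 5)
#' @export
simulate_core <- function(grid, bias = NULL, clones = list(),
                          params = core_params(), t_end = 300,
                          dt = 0.01, save_dt = 1, tol_ss = 1e-8,
                          init_noise = 0, seed = NULL,
                          engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  n <- grid$n_cells
  p <- params
  if (t_end <= 0 || dt <= 0 || save_dt <= 0)
    stop_param("t_end, dt and save_dt must be > 0")
  m <- if (is.null(bias)) matrix(1 / 6, n, 6) else bias$m
  if (!all(dim(m) == c(n, 6))) stop_param("bias does not match grid")

  fz_tot <- rep(p$fz_total, n); vang_tot <- rep(p$vang_total, n)
  dsh_tot <- rep(p$dsh_total, n); pk_tot <- rep(p$pk_total, n)
  for (cl in clones) {
    stopifnot(inherits(cl, "clone_spec"))
    if (any(cl$cells < 1 | cl$cells > n)) stop_param("clone cells outside grid")
    switch(cl$species,
      fz = { fz_tot[cl$cells] <- 0 },
      dsh = { dsh_tot[cl$cells] <- 0 },
      vang = { vang_tot[cl$cells] <- 0 },
      pk = { pk_tot[cl$cells] <- 0 },
      stop_param("clone species '%s' acts on the Ft-Ds layer; pass it to solve_ftds_layer",
                 cl$species))
  }

  s0 <- core_initial_state(n, fz_tot, vang_tot, dsh_tot, pk_tot)
  if (init_noise > 0) {
    if (is.null(seed)) stop_param("init_noise > 0 requires a seed")
    set.seed(seed)
    s0$Fz <- s0$Fz * (1 + init_noise * (stats::runif(n * 6) - 0.5))
  }
  y <- core_pack(s0)

  ctx <- list(n = n, p = p, part = grid$partner, m = m,
              eL = c(6, 1:5), eR = c(2:6, 1))
  part_int <- as.integer(grid$partner)
  m_vec <- as.numeric(m)
  pv <- core_par_vec(p)
  rhs <- if (engine == "compiled") {
    function(y) core_rhs_cpp(y, n, part_int, m_vec, pv)
  } else {
    function(y) core_rhs(y, ctx)
  }

  n_save <- floor(t_end / save_dt + 1e-9)
  steps_per_save <- max(1L, round(save_dt / dt))
  h <- save_dt / steps_per_save  # exact subdivision of the save interval

  times <- numeric(n_save + 1L)
  P <- array(NA_real_, c(n_save + 1L, n, 2))
  s <- core_unpack(y, n)
  P[1L, , ] <- polarity_vectors(s, grid)
  times[1L] <- 0
  steady <- FALSE
  max_dydt <- NA_real_
  t <- 0
  k_save <- 1L
  while (k_save <= n_save && !steady) {
    for (st in seq_len(steps_per_save)) {
      k1v <- rhs(y)
      k2v <- rhs(y + h / 2 * k1v)
      k3v <- rhs(y + h / 2 * k2v)
      k4v <- rhs(y + h * k3v)
      y <- y + h / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    }
    t <- t + save_dt
    k_save <- k_save + 1L
    s <- core_unpack(y, n)
    P[k_save, , ] <- polarity_vectors(s, grid)
    times[k_save] <- t
    dydt <- rhs(y)
    max_dydt <- max(abs(dydt))
    if (max_dydt < tol_ss) steady <- TRUE
  }
  keep <- seq_len(k_save)
  s <- core_unpack(y, n)
  if (min(core_pack(s)) < -1e-8)
    stop(sprintf("integrator failure: negative concentration (min %.3g) at t = %.3g",
                 min(core_pack(s)), t), call. = FALSE)
  if (anyNA(core_pack(s)))
    stop(sprintf("integrator failure: NaN in state at t = %.3g", t),
         call. = FALSE)

  totals <- conserved_totals(s, grid)
  structure(
    list(times = times[keep], P = P[keep, , , drop = FALSE],
         magnitude = sqrt(P[keep, , 1, drop = FALSE]^2 +
                          P[keep, , 2, drop = FALSE]^2)[, , 1],
         state = s, steady = steady, max_dydt = max_dydt,
         totals = totals, clones = clones,
         grid = grid, bias = bias, params = p, dt = h, save_dt = save_dt),
    class = "pcp_sim")
}

#' Per-cell conserved totals of a core state
#'
#' Dsh: cytoplasmic + membrane (free and complexed, incl. Dsh in bridges);
#' Fz: membrane free + Dsh-Fz + bridges (Fz side); Vang: cytoplasmic +
#' membrane free + Pk-Vang + bridges whose Vang side is this cell; Pk:
#' cytoplasmic + Pk-Vang.
#'
#' @param s a core state list (e.g. `sim$state`).
#' @param grid the [hex_grid()].
#' @return data.frame with columns `dsh`, `fz`, `vang`, `pk` (one row per
#'   cell).
#' @export
conserved_totals <- function(s, grid) {
  n <- grid$n_cells
  bridges <- s$B0 + s$BD
  bridges_vang_side <- matrix(bridges[grid$partner], n, 6)
  data.frame(
    dsh = s$DshC + rowSums(s$Dm + s$DF + s$BD),
    fz = rowSums(s$Fz + s$DF + bridges),
    vang = s$VangC + rowSums(s$Vm + s$PV + bridges_vang_side),
    pk = s$PkC + rowSums(s$PV))
}

#' @export
print.pcp_sim <- function(x, ...) {
  n_t <- length(x$times)
  cat(sprintf("pcp_sim: %d x %d grid, t = 0..%.4g (%s)\n",
              x$grid$n_rows, x$grid$n_cols, x$times[n_t],
              if (x$steady) "steady state" else
                sprintf("max|dy/dt| = %.2g", x$max_dydt)))
  cat(sprintf("  final mean |P| = %.4g\n", mean(x$magnitude[n_t, ])))
  invisible(x)
}

#' @export
summary.pcp_sim <- function(object, ...) {
  n_t <- length(object$times)
  mag <- object$magnitude[n_t, ]
  ang <- wrap360(rad2deg(atan2(object$P[n_t, , 2], object$P[n_t, , 1])))
  out <- list(t_end = object$times[n_t], steady = object$steady,
              mean_magnitude = mean(mag),
              mean_angle_deg = circ_mean(ang, w = mag)$mean_deg,
              by_column = data.frame(
                column = seq_len(object$grid$n_cols),
                magnitude = column_means(object$grid, mag)))
  class(out) <- "summary.pcp_sim"
  out
}

#' @export
print.summary.pcp_sim <- function(x, ...) {
  cat(sprintf("steady = %s, t_end = %.4g\n", x$steady, x$t_end))
  cat(sprintf("mean |P| = %.4g, mean angle = %.1f deg\n",
              x$mean_magnitude, x$mean_angle_deg))
  invisible(x)
}

#' Polarity readout table of a simulation
#'
#' Per-cell polarity magnitude and angle at the final time, plus the combined
#' quantity of membrane Dsh on the two sides of every shared cell boundary
#' (what a light micrograph of Dsh would show at each junction). Suitable for
#' drawing hair-like polarity vectors scaled by the Dsh vector sum.
#'
#' @param sim a [simulate_core()] result.
#' @return list with `cells` (data.frame: cell, row, col, px, py, magnitude,
#'   angle_deg) and `boundaries` (data.frame: cell, edge, neighbor,
#'   dsh_combined).
#' @export
render_polarity <- function(sim) {
  grid <- sim$grid
  n_t <- length(sim$times)
  px <- sim$P[n_t, , 1]; py <- sim$P[n_t, , 2]
  mag <- sqrt(px^2 + py^2)
  ang <- ifelse(mag > 0, wrap360(rad2deg(atan2(py, px))), 0)
  md <- membrane_dsh(sim$state)
  md_across <- matrix(md[grid$partner], grid$n_cells, 6)
  comb <- md + md_across
  bdry <- data.frame(
    cell = rep(seq_len(grid$n_cells), 6),
    edge = rep(1:6, each = grid$n_cells),
    neighbor = as.integer(grid$nbr),
    dsh_combined = as.numeric(comb))
  list(cells = data.frame(cell = seq_len(grid$n_cells),
                          row = grid$row, col = grid$col,
                          px = px, py = py,
                          magnitude = mag, angle_deg = ang),
       boundaries = bdry[!is.na(bdry$neighbor), ])
}

#' Plot the polarity field as hair-like vectors
#' @param x a [simulate_core()] result.
#' @param scale hair length per unit polarity magnitude.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the readout table.
#' @export
plot.pcp_sim <- function(x, scale = 0.8, ...) {
  ro <- render_polarity(x)$cells
  g <- x$grid
  graphics::plot(g$cx, g$cy, asp = 1, pch = 16, cex = 0.3,
                 xlab = "x (distal →)", ylab = "y",
                 ylim = rev(range(g$cy)), ...)
  mmax <- max(ro$magnitude, 1e-12)
  graphics::arrows(g$cx, g$cy,
                   g$cx + scale * ro$px / mmax,
                   g$cy + scale * ro$py / mmax,
                   length = 0.03)
  invisible(ro)
}

#' Polarization kinetics by grid column
#'
#' Mean polarity magnitude over time for requested columns, plus `t90`: the
#' first saved time at which the column mean reaches 90 percent of its final
#' value (linearly interpolated between snapshots).
#'
#' @param sim a [simulate_core()] result.
#' @param columns column indices (default: all).
#' @return list with `times`, `mean_P` (time x column matrix), `t90` (named
#'   vector), `steady` flag (carries a warning flag when the simulation did
#'   not reach steady state).
#' @export
polarization_kinetics <- function(sim, columns = NULL) {
  grid <- sim$grid
  if (is.null(columns)) columns <- seq_len(grid$n_cols)
  n_t <- length(sim$times)
  mP <- sapply(columns, function(cc) {
    cells <- cells_in_columns(grid, cc)
    rowMeans(sim$magnitude[, cells, drop = FALSE])
  })
  mP <- matrix(mP, nrow = n_t)
  colnames(mP) <- as.character(columns)
  t90 <- vapply(seq_along(columns), function(k) {
    v <- mP[, k]
    target <- 0.9 * v[n_t]
    if (v[n_t] <= 0) return(NA_real_)
    i <- which(v >= target)[1]
    if (is.na(i) || i == 1L) return(sim$times[max(i, 1L)])
    # linear interpolation within the bracketing save interval
    f <- (target - v[i - 1L]) / (v[i] - v[i - 1L])
    sim$times[i - 1L] + f * (sim$times[i] - sim$times[i - 1L])
  }, numeric(1))
  names(t90) <- as.character(columns)
  if (!sim$steady)
    warning("simulation did not reach steady state; t90 values are provisional")
  list(times = sim$times, mean_P = mP, t90 = t90, steady = sim$steady)
}

#' One-call pipeline: gradients to polarity
#'
#' Convenience wrapper chaining [solve_ftds_layer()], [mt_bias_from_ftds()]
#' and [simulate_core()], applying `ft`/`ds` clones to the layer and core
#' clones to the reaction network.
#'
#' @param grid a [hex_grid()].
#' @param ds,fj gradients (see [make_gradient()]).
#' @param clones list of [clone_spec()].
#' @param mt_mode mode string or per-cell vector for [mt_bias_from_ftds()].
#' @param ftds_par,core_par parameter lists.
#' @param ... passed to [simulate_core()] (`t_end`, `dt`, ...).
#' @return a `pcp_sim` (with `$layer` attached).
#' @export
pcp_pipeline <- function(grid, ds, fj = 0.5, clones = list(),
                         mt_mode = "coupled",
                         ftds_par = ftds_params(), core_par = core_params(),
                         ...) {
  ft_tot <- rep(ftds_par$ft_total, grid$n_cells)
  ds_tot <- per_cell_levels(grid, ds, "Ds gradient")
  layer_clones <- Filter(function(cl) cl$species %in% c("ft", "ds"), clones)
  core_clones <- Filter(function(cl) !cl$species %in% c("ft", "ds"), clones)
  for (cl in layer_clones) {
    if (cl$species == "ft") ft_tot[cl$cells] <- 0 else ds_tot[cl$cells] <- 0
  }
  layer <- solve_ftds_layer(grid, ds_tot, fj, ftds_par, ft_total = ft_tot)
  bias <- mt_bias_from_ftds(layer, mode = mt_mode)
  sim <- simulate_core(grid, bias, clones = core_clones, params = core_par,
                       ...)
  sim$layer <- layer
  sim
}
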