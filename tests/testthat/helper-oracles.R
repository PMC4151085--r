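## Independent oracle routines used across the suite. These deliberately do
## not share code with the package implementation.

## circular mean of axial angles via complex arithmetic on doubled angles
oracle_axial_mean <- function(deg) {
  z <- mean(exp(2i * deg * pi / 180))
  (Arg(z) * 180 / pi / 2) %% 180
}

oracle_resultant <- function(deg, axial = FALSE) {
  k <- if (axial) 2 else 1
  Mod(mean(exp(1i * k * deg * pi / 180)))
}

## exact two-sided binomial p by direct enumeration of the pmf
oracle_binom_p <- function(x, n, p = 0.5) {
  probs <- dbinom(0:n, n, p)
  sum(probs[probs <= dbinom(x, n, p) * (1 + 1e-7)])
}

## brute-force net-direction classifier over a displacement vector
oracle_direction <- function(vx, vy) {
  if (vx == 0 && vy == 0) return("zero")
  if (abs(vx) >= abs(vy)) {
    if (vx >= 0) "distal" else "proximal"
  } else {
    if (vy > 0) "posterior" else "anterior"
  }
}

## brute-force Ft-Ds equilibrium on an arbitrary grid by tiny explicit
## Euler steps of the binding kinetics (independent of the package solver)
oracle_ftds <- function(grid, ds_tot, fj, ft_tot, k_on = 1, k_off = 1,
                        alpha_F = 1, alpha_D = 1, n_steps = 400000,
                        dt = 0.002) {
  n <- grid$n_cells
  H <- matrix(0, n, 6)
  aF <- 1 + alpha_F * fj
  aD <- 1 / (1 + alpha_D * fj)
  part_cell <- matrix(((grid$partner - 1) %% n) + 1, n, 6)
  for (it in seq_len(n_steps)) {
    ft_free <- pmax(ft_tot - rowSums(H), 0)
    ds_bound <- rowSums(matrix(H[grid$partner], n, 6))
    ds_free <- pmax(ds_tot - ds_bound, 0)
    rate <- k_on * aF * matrix(aD[part_cell], n, 6) * ft_free *
      matrix(ds_free[part_cell], n, 6) - k_off * H
    H <- H + dt * rate
    if (max(abs(rate)) < 1e-13) break
  }
  H
}

## straight-line two-channel toy images for shift-correlation checks
oracle_shifted_pair <- function(w = 60, h = 40, offset = 5, seed = 1) {
  set.seed(seed)
  a <- matrix(rnorm(w * h), h, w)
  k <- exp(-outer(-4:4, -4:4, function(i, j) (i^2 + j^2) / 8))
  # light smoothing so the correlation peak has curvature
  sm <- function(m) {
    out <- m * 0
    for (di in -4:4) for (dj in -4:4) {
      ii <- pmin(pmax(seq_len(h) + di, 1), h)
      jj <- pmin(pmax(seq_len(w) + dj, 1), w)
      out <- out + k[di + 5, dj + 5] * m[ii, jj]
    }
    out
  }
  a <- sm(a)
  b <- a * 0
  if (offset >= 0) b[, (1 + offset):w] <- a[, 1:(w - offset)]
  else b[, 1:(w + offset)] <- a[, (1 - offset):w]
  list(a = a, b = b)
}
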