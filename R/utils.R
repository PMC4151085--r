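#' @keywords internal
#' @useDynLib wingpol, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## Shared numeric helpers. Angle conventions used package-wide:
##  - image/grid coordinates: origin top-left, x rightward (+x = distal),
##    y downward (+y = posterior); angles measured from +x toward +y.
##  - axial (undirected) angles live in [0, 180); circular statistics on
##    axial data are computed on doubled angles.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Wrap angles into [0, 360) degrees
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped to [0, 360).
#' @keywords internal
wrap360 <- function(x) x %% 360

#' Wrap axial angles into [0, 180) degrees
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped to [0, 180).
#' @keywords internal
wrap180 <- function(x) x %% 180

stop_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Circular mean and resultant length
#'
#' Mean direction and mean resultant length R of a sample of circular data.
#' For axial data (undirected orientations in `[0, 180)`) set `axial = TRUE`:
#' statistics are then computed on doubled angles and the mean is mapped back
#' to `[0, 180)`.
#'
#' @param angles_deg numeric vector of angles in degrees.
#' @param w optional non-negative weights.
#' @param axial logical; treat input as axial data on `[0, 180)`.
#' @return list with `mean_deg` and `R` (resultant length in `[0, 1]`).
#' @examples
#' circ_mean(c(10, 20, 30))
#' circ_mean(c(0, 90), axial = TRUE)  # antipodal after doubling: R = 0
#' @export
circ_mean <- function(angles_deg, w = NULL, axial = FALSE) {
  if (length(angles_deg) == 0L) stop_param("empty angle vector")
  if (is.null(w)) w <- rep(1, length(angles_deg))
  if (any(w < 0)) stop_param("weights must be non-negative")
  sw <- sum(w)
  if (sw <= 0) stop_param("weights sum to zero")
  mult <- if (axial) 2 else 1
  a <- deg2rad(angles_deg * mult)
  C <- sum(w * cos(a)) / sw
  S <- sum(w * sin(a)) / sw
  R <- sqrt(C^2 + S^2)
  mu <- rad2deg(atan2(S, C)) / mult
  mu <- if (axial) wrap180(mu) else wrap360(mu)
  list(mean_deg = mu, R = R)
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler. `kappa = 0` reduces to the uniform
#' distribution on the circle.
#'
#' @param n number of draws.
#' @param mu_deg mean direction in degrees.
#' @param kappa concentration parameter, `>= 0`.
#' @return angles in degrees in `[0, 360)`.
#' @export
rvonmises <- function(n, mu_deg = 0, kappa = 1) {
  if (kappa < 0) stop_param("kappa must be >= 0")
  if (n == 0L) return(numeric(0))
  if (kappa == 0) return(wrap360(stats::runif(n, 0, 360)))
  mu <- deg2rad(mu_deg)
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    th <- sign(u3[ok] - 0.5) * acos(f[ok])
    k <- sum(ok)
    if (k > 0) {
      out[(got + 1L):(got + k)] <- th
      got <- got + k
    }
  }
  wrap360(rad2deg(out + mu))
}

## ---- separable filtering with reflective padding ----------------------

gauss_kernel <- function(sigma, deriv = 0L) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (deriv == 0L) return(g)
  # first derivative of the Gaussian (d/dx)
  (-x / sigma^2) * g
}

reflect_idx <- function(n, r) {
  # indices for reflective (mirror, no repeat of edge sample) padding
  idx <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
  pmin(pmax(idx, 1L), n)
}

conv1d_rows <- function(m, k) {
  # convolve each column along row index (y direction)
  r <- (length(k) - 1L) %/% 2L
  idx <- reflect_idx(nrow(m), r)
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(k)) {
    out <- out + k[j] * mp[seq_len(nrow(m)) + (j - 1L), , drop = FALSE]
  }
  out
}

#' Separable filtering of an image with reflective padding
#'
#' Applies 1-D kernels along y (rows) and x (columns). Used for Gaussian and
#' Gaussian-derivative filtering throughout the package.
#'
#' @param img numeric matrix (row = y, column = x).
#' @param ky,kx 1-D kernels (odd length); either may be `NULL` to skip.
#' @return filtered matrix, same dimensions.
#' @keywords internal
filter_sep <- function(img, ky = NULL, kx = NULL) {
  out <- img
  if (!is.null(ky)) out <- conv1d_rows(out, ky)
  if (!is.null(kx)) out <- t(conv1d_rows(t(out), kx))
  out
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gauss_kernel(sigma)
  filter_sep(img, k, k)
}

#' Derive a stream of child seeds from one master seed
#'
#' Deterministic fan-out so that one user-facing seed controls every stage of
#' a pipeline run independently. Children stay below 2^31.
#'
#' @param seed integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
child_seeds <- function(seed, n) {
  s <- as.double(seed) %% 2147483647
  out <- numeric(n)
  for (i in seq_len(n)) {
    # Lehmer / Park-Miller step
    s <- (s * 48271) %% 2147483647
    out[i] <- s
  }
  as.integer(out)
}
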