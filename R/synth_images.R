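## Synthetic image generators with machine-readable ground truth.
##
## Image convention: matrices with row = y (down), column = x (right);
## pixel centers at integer coordinates; +x = distal, +y = posterior.

## accumulate an anti-aliased line segment (Gaussian cross-profile) into img
render_segment <- function(img, x0, y0, x1, y1, width = 1.2, amp = 1) {
  h <- nrow(img); w <- ncol(img)
  pad <- ceiling(3 * width)
  xmin <- max(1L, floor(min(x0, x1)) - pad)
  xmax <- min(w, ceiling(max(x0, x1)) + pad)
  ymin <- max(1L, floor(min(y0, y1)) - pad)
  ymax <- min(h, ceiling(max(y0, y1)) + pad)
  if (xmin > xmax || ymin > ymax) return(img)
  xs <- xmin:xmax; ys <- ymin:ymax
  px <- matrix(rep(xs, each = length(ys)), length(ys))
  py <- matrix(rep(ys, times = length(xs)), length(ys))
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx^2 + dy^2
  t <- if (len2 == 0) 0 else pmin(pmax(((px - x0) * dx + (py - y0) * dy) / len2, 0), 1)
  d2 <- (px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2
  img[ys, xs] <- img[ys, xs] + amp * exp(-d2 / (2 * width^2))
  img
}

render_gaussian_spot <- function(img, x0, y0, sigma = 1.5, amp = 1) {
  render_segment(img, x0, y0, x0, y0, width = sigma, amp = amp)
}

#' Synthetic fiber (microtubule-like) image
#'
#' Renders anti-aliased line segments whose axial orientations follow a von
#' Mises distribution on doubled angles (the axial analogue of a von Mises),
#' blurs them and adds Gaussian read noise. The sampled truth angles are
#' returned alongside the image so downstream orientation estimates can be
#' scored. `kappa = 0` gives uniformly oriented fibers.
#'
#' @param n_fibers number of fibers.
#' @param mu_deg mean axial angle in degrees, in `[0, 180)`.
#' @param kappa concentration on doubled angles (>= 0).
#' @param size image side in pixels (>= 64).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param fiber_length mean fiber length in pixels.
#' @param blur_sigma Gaussian blur applied after rendering.
#' @param seed RNG seed; same seed and parameters give a bit-identical image.
#' @return object of class `fiber_image_truth`: list with `image` (size x
#'   size, non-negative), `fiber_angles` (degrees in `[0, 180)`), `mu_deg`,
#'   `kappa`, `seed`.
#' @examples
#' fi <- make_fiber_image(40, mu_deg = 30, kappa = 20, size = 96, seed = 1)
#' range(fi$fiber_angles)
#' @export
make_fiber_image <- function(n_fibers, mu_deg = 0, kappa = 8, size = 256,
                             noise_sd = 0.05, fiber_length = size / 4,
                             blur_sigma = 1, seed = 1) {
  if (size < 64) stop_param("size must be >= 64")
  if (noise_sd < 0) stop_param("noise_sd must be >= 0")
  if (kappa < 0) stop_param("kappa must be >= 0")
  set.seed(seed)
  # axial von Mises: sample doubled angles, halve
  theta <- wrap180(rvonmises(n_fibers, mu_deg = 2 * mu_deg, kappa = kappa) / 2)
  img <- matrix(0, size, size)
  cx <- stats::runif(n_fibers, 1, size)
  cy <- stats::runif(n_fibers, 1, size)
  len <- pmax(4, stats::rnorm(n_fibers, fiber_length, fiber_length / 4))
  for (i in seq_len(n_fibers)) {
    dx <- cos(deg2rad(theta[i])) * len[i] / 2
    dy <- sin(deg2rad(theta[i])) * len[i] / 2
    img <- render_segment(img, cx[i] - dx, cy[i] - dy, cx[i] + dx, cy[i] + dy)
  }
  img <- gaussian_blur(img, blur_sigma)
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(size^2, 0, noise_sd), size)
  img <- pmax(img, 0)
  structure(list(image = img, fiber_angles = theta, mu_deg = mu_deg,
                 kappa = kappa, seed = seed),
            class = "fiber_image_truth")
}

#' Paired dot (tubulin-like) and membrane (Dsh-like) channels
#'
#' Renders a field of hexagonal cells: channel `membrane` draws the cell
#' outlines, channel `dots` one spot per cell displaced by `offset_px` toward
#' proximal (-x direction rotated by `axis_deg`) from the centroid, emulating
#' the proximal bias of apical tubulin dots. With zero offset the downstream
#' shift-correlation profile is symmetric; with a proximal offset the
#' proximal peak sits closer than the distal one.
#'
#' @param grid a [hex_grid()] supplying cell geometry.
#' @param offset_px dot displacement in pixels; `|offset_px|` must be below
#'   half a cell diameter.
#' @param axis_deg P-D axis direction in degrees (0 = +x).
#' @param cell_px cell width (twice the apothem) in pixels.
#' @param noise_sd Gaussian noise added to both channels.
#' @param seed RNG seed (noise only; geometry is deterministic).
#' @return list with `dots`, `membrane` (matrices), `offset_px`, `axis_deg`,
#'   `cell_px`, `apothem_px`, `centers` (data.frame of pixel centroids),
#'   `seed`.
#' @export
make_dot_membrane_pair <- function(grid, offset_px = 4, axis_deg = 0,
                                   cell_px = 20, noise_sd = 0, seed = 1) {
  apothem <- cell_px / 2
  if (abs(offset_px) >= apothem)
    stop_param("|offset_px| must be smaller than half a cell diameter (%g px)",
               apothem)
  set.seed(seed)
  # pixel geometry: scale unit grid coordinates by cell_px, margin one cell
  sx <- grid$cx * cell_px + cell_px
  sy <- grid$cy * cell_px + cell_px
  w <- ceiling(max(sx) + cell_px)
  h <- ceiling(max(sy) + cell_px)
  membrane <- matrix(0, h, w)
  dots <- matrix(0, h, w)
  rc <- cell_px / sqrt(3)  # circumradius of pointy-top hexagon
  vang <- deg2rad(c(30, 90, 150, 210, 270, 330))
  for (i in seq_len(grid$n_cells)) {
    vx <- sx[i] + rc * cos(vang)
    vy <- sy[i] + rc * sin(vang)
    for (k in 1:6) {
      k2 <- if (k == 6) 1 else k + 1
      membrane <- render_segment(membrane, vx[k], vy[k], vx[k2], vy[k2],
                                 width = 1.0)
    }
    dots <- render_gaussian_spot(dots,
                                 sx[i] - offset_px * cos(deg2rad(axis_deg)),
                                 sy[i] - offset_px * sin(deg2rad(axis_deg)),
                                 sigma = 1.5)
  }
  if (noise_sd > 0) {
    membrane <- pmax(membrane + matrix(stats::rnorm(h * w, 0, noise_sd), h), 0)
    dots <- pmax(dots + matrix(stats::rnorm(h * w, 0, noise_sd), h), 0)
  }
  list(dots = dots, membrane = membrane, offset_px = offset_px,
       axis_deg = axis_deg, cell_px = cell_px, apothem_px = apothem,
       centers = data.frame(x = sx, y = sy), seed = seed)
}
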