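## Angular statistics of microtubule anchoring sites around cell centroids.
## Input is either a vector of angles (0 = distal = +x) or traced point
## coordinates with per-cell centroids.

#' Angles of anchoring sites from traced point coordinates
#'
#' @param df data.frame with columns `cell_id`, `centroid_x`, `centroid_y`,
#'   `site_x`, `site_y` (pixel coordinates, y down).
#' @return numeric vector of angles in `[0, 360)` relative to the centroid,
#'   0 degrees = distal (+x).
#' @export
anchoring_angles_from_points <- function(df) {
  need <- c("cell_id", "centroid_x", "centroid_y", "site_x", "site_y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_param("missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop_param("empty anchoring table")
  wrap360(rad2deg(atan2(df$site_y - df$centroid_y,
                        df$site_x - df$centroid_x)))
}

#' Circular histogram of anchoring-site angles
#'
#' Counts per angular bin around the full circle; default 20 bins of 18
#' degrees, bin k covering `[k*w, (k+1)*w)` from 0 = distal.
#'
#' @param angles_deg numeric vector of angles in degrees.
#' @param n_bins number of bins; `n_bins * bin_width = 360`.
#' @param normalize divide counts by the total.
#' @return list with `breaks_deg`, `mid_deg`, `counts` (or frequencies),
#'   `n_bins`, `bin_width`, `n`.
#' @export
anchoring_histogram <- function(angles_deg, n_bins = 20, normalize = FALSE) {
  if (length(angles_deg) == 0) stop_param("empty anchoring-site set")
  bin_width <- 360 / n_bins
  a <- wrap360(angles_deg)
  bin <- pmin(floor(a / bin_width), n_bins - 1L) + 1L
  counts <- tabulate(bin, nbins = n_bins)
  list(breaks_deg = seq(0, 360, by = bin_width),
       mid_deg = seq(bin_width / 2, 360 - bin_width / 2, by = bin_width),
       counts = if (normalize) counts / sum(counts) else counts,
       n_bins = n_bins, bin_width = bin_width, n = length(a))
}

#' Proximal-distal bias statistics of anchoring sites
#'
#' Three complementary readouts of P-D polarization of anchoring-site
#' placement: the raw circular resultant (directional bias; 0 for a
#' perfectly balanced proximal/distal bimodal), the axial resultant on
#' doubled angles (axis alignment; 1 for that same bimodal), and the
#' half-plane count comparison with an exact two-sided binomial test.
#' Sites exactly on the +/-90 degree boundary (`cos(angle) == 0` within
#' tolerance) belong to neither half-plane and are dropped from the
#' binomial; their number is reported.
#'
#' @param angles_deg anchoring-site angles in degrees (0 = distal).
#' @param tol tolerance on `cos(angle)` for the boundary tie rule.
#' @return list with `raw` (`mean_deg`, `R`), `axial` (`mean_deg`, `R` on
#'   doubled angles, axis mapped to `[0, 180)`), `n_distal`, `n_proximal`,
#'   `n_dropped`, `binomial_p`.
#' @examples
#' axial_bias_stats(c(rep(0, 30), rep(180, 10)))
#' @export
axial_bias_stats <- function(angles_deg, tol = 1e-9) {
  if (length(angles_deg) == 0) stop_param("empty anchoring-site set")
  a <- wrap360(angles_deg)
  raw <- circ_mean(a)
  axial <- circ_mean(wrap180(a), axial = TRUE)
  cs <- cos(deg2rad(a))
  distal <- cs > tol
  proximal <- cs < -tol
  nd <- sum(distal); np <- sum(proximal)
  p <- if (nd + np == 0) NA_real_ else
    stats::binom.test(nd, nd + np, p = 0.5,
                      alternative = "two.sided")$p.value
  list(raw = raw, axial = axial,
       n_distal = nd, n_proximal = np,
       n_dropped = length(a) - nd - np,
       binomial_p = p)
}
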