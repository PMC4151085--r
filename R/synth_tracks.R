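## Synthetic vesicle tracks and anchoring-site angles with ground truth.

#' Synthetic mixture of vesicle tracks
#'
#' Emulates live-imaging vesicle tracks sampled at fixed frame intervals
#' (default 5 s): *transcytotic* tracks drift persistently along the P-D
#' axis (distal with probability `p_distal`) with small lateral noise;
#' *wandering* tracks are unbiased random walks with pause frames; *stuck*
#' tracks show zero displacement in every frame. Tracks carry their
#' generating mode as ground truth.
#'
#' @param n number of tracks.
#' @param f_trans,f_wander,f_stuck mode fractions; must sum to 1 (tol 1e-9).
#' @param p_distal probability a transcytotic track drifts distal (+x).
#' @param step_px per-frame drift step of transcytotic tracks (pixels).
#' @param n_frames frames per track (>= 2).
#' @param frame_interval_s seconds between frames (default 5).
#' @param lateral_sd lateral noise of transcytotic tracks.
#' @param pause_prob pause probability per step for wandering tracks.
#' @param seed RNG seed.
#' @return object of class `track_mixture_truth`: list with `tracks` (a
#'   data.frame: track_id, frame, t_seconds, x, y, truth_label, apical),
#'   `labels` (per-track mode), `p_distal`, `frame_interval_s`, `seed`.
#' @examples
#' tm <- make_track_mixture(50, 0.6, 0.3, 0.1, seed = 1)
#' table(tm$labels)
#' @export
make_track_mixture <- function(n, f_trans = 0.7, f_wander = 0.2,
                               f_stuck = 0.1, p_distal = 0.75,
                               step_px = 2, n_frames = 8,
                               frame_interval_s = 5,
                               lateral_sd = 0.3, pause_prob = 0.3,
                               seed = 1) {
  if (abs(f_trans + f_wander + f_stuck - 1) > 1e-9)
    stop_param("mode fractions must sum to 1")
  if (n_frames < 2) stop_param("n_frames must be >= 2")
  if (frame_interval_s <= 0) stop_param("frame_interval_s must be > 0")
  set.seed(seed)
  labels <- sample(rep(c("transcytotic", "wandering", "stuck"),
                       times = round(n * c(f_trans, f_wander, f_stuck)))[
                         seq_len(n)])
  # rounding can under-fill; top up with the majority mode
  labels[is.na(labels)] <- "transcytotic"
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    x0 <- stats::runif(1, 0, 200); y0 <- stats::runif(1, 0, 200)
    lab <- labels[i]
    if (lab == "stuck") {
      x <- rep(x0, n_frames); y <- rep(y0, n_frames)
    } else if (lab == "transcytotic") {
      dir <- if (stats::runif(1) < p_distal) 1 else -1
      dx <- dir * step_px * (1 + stats::rnorm(n_frames - 1, 0, 0.1))
      dy <- stats::rnorm(n_frames - 1, 0, lateral_sd)
      x <- x0 + c(0, cumsum(dx)); y <- y0 + c(0, cumsum(dy))
    } else { # wandering
      pause <- stats::runif(n_frames - 1) < pause_prob
      dx <- ifelse(pause, 0, stats::rnorm(n_frames - 1, 0, step_px / 2))
      dy <- ifelse(pause, 0, stats::rnorm(n_frames - 1, 0, step_px / 2))
      x <- x0 + c(0, cumsum(dx)); y <- y0 + c(0, cumsum(dy))
    }
    rows[[i]] <- data.frame(
      track_id = i, frame = seq_len(n_frames),
      t_seconds = (seq_len(n_frames) - 1) * frame_interval_s,
      x = x, y = y, truth_label = lab, apical = TRUE)
  }
  structure(list(tracks = do.call(rbind, rows), labels = labels,
                 p_distal = p_distal, frame_interval_s = frame_interval_s,
                 seed = seed),
            class = "track_mixture_truth")
}

#' Synthetic microtubule anchoring-site angles
#'
#' Angles of anchoring sites around the cell centroid, drawn from an
#' equal-weight mixture of von Mises modes on the full circle. With modes at
#' 0 and 180 degrees this emulates the proximal/distal junctional bias of
#' anchoring sites; `kappa = 0` gives a uniform circular sample.
#'
#' @param n number of sites (>= 1).
#' @param modes_deg mode directions in degrees (non-empty).
#' @param kappa shared von Mises concentration (>= 0).
#' @param seed RNG seed.
#' @return numeric vector of angles in `[0, 360)`.
#' @export
make_anchoring_angles <- function(n, modes_deg = c(0, 180), kappa = 4,
                                  seed = 1) {
  if (n < 1) stop_param("n must be >= 1")
  if (length(modes_deg) == 0) stop_param("modes_deg must be non-empty")
  set.seed(seed)
  which_mode <- sample(seq_along(modes_deg), n, replace = TRUE)
  out <- numeric(n)
  for (k in seq_along(modes_deg)) {
    idx <- which(which_mode == k)
    if (length(idx)) out[idx] <- rvonmises(length(idx), modes_deg[k], kappa)
  }
  wrap360(out)
}
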