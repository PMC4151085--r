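## Vesicle-track quantification: filtering, net-direction classification
## (proximal/distal/anterior/posterior/stuck), motion-mode classification
## (transcytotic vs wandering) and the proximal-vs-distal binomial test.
##
## Tracks are data.frames with columns track_id, frame, t_seconds, x, y and
## optionally apical (logical) and extra columns, one row per frame.

split_tracks <- function(tracks) {
  split(tracks, tracks$track_id)
}

#' Filter tracks by minimum consecutive in-plane frames
#'
#' A vesicle is analyzable only if visible in at least `min_frames`
#' consecutive frames (default 2) in the apical plane (at the level of the
#' adherens junctions). The longest consecutive apical run of each track is
#' kept; tracks whose longest run is shorter are dropped.
#'
#' @param tracks track data.frame (see package conventions above).
#' @param min_frames minimum consecutive frames (default 2).
#' @param require_apical if `TRUE` (default) only frames with
#'   `apical == TRUE` count (tracks without an `apical` column are treated
#'   as fully apical).
#' @return filtered track data.frame (possibly empty).
#' @export
filter_tracks <- function(tracks, min_frames = 2, require_apical = TRUE) {
  keep <- lapply(split_tracks(tracks), function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    ok <- if (require_apical && "apical" %in% names(tr)) tr$apical
          else rep(TRUE, nrow(tr))
    ## runs restart where the apical flag breaks or frame numbers jump
    grp <- cumsum(!ok | c(TRUE, diff(tr$frame) != 1L))
    lens <- tapply(ok, grp, sum)
    if (max(lens) < min_frames) return(NULL)
    best <- as.integer(names(lens)[which.max(lens)])
    tr[grp == best & ok, , drop = FALSE]
  })
  out <- do.call(rbind, keep)
  if (is.null(out)) tracks[0, , drop = FALSE] else out
}

#' Net-direction category of one track
#'
#' A track is *stuck* when every consecutive displacement is at most
#' `stuck_eps` (pixel-exact with the default `stuck_eps = 0`, matching
#' manual scoring of "no change in location between any two consecutive
#' frames"). Otherwise the net vector `v` from the first to the last point
#' decides: axial (`|v_x| >= |v_y|`, ties to the axial class) gives
#' *distal* (`v_x >= 0`) or *proximal*; else *posterior* (`v_y > 0`, y
#' points down) or *anterior*.
#'
#' @param track data.frame of one track's frames (ordered or not).
#' @param stuck_eps displacement threshold in pixels.
#' @return one of `"stuck"`, `"proximal"`, `"distal"`, `"anterior"`,
#'   `"posterior"`.
#' @export
classify_net_direction <- function(track, stuck_eps = 0) {
  tr <- track[order(track$frame), , drop = FALSE]
  if (nrow(tr) < 2) stop_param("track has fewer than 2 frames")
  steps <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  if (all(steps <= stuck_eps)) return("stuck")
  vx <- tr$x[nrow(tr)] - tr$x[1]
  vy <- tr$y[nrow(tr)] - tr$y[1]
  if (abs(vx) >= abs(vy)) {
    if (vx >= 0) "distal" else "proximal"
  } else {
    if (vy > 0) "posterior" else "anterior"
  }
}

#' Direction summary of a set of tracks
#'
#' Classifies every track with [classify_net_direction()] and tabulates
#' counts and fractions. The axial fraction is `(proximal + distal) /
#' n_total` with all filtered tracks (including stuck) in the denominator;
#' the stuck-excluded variant is also reported. Distal vs proximal counts
#' are compared with the exact binomial test against 0.5.
#'
#' @param tracks filtered track data.frame.
#' @param stuck_eps passed to [classify_net_direction()].
#' @param alternative binomial-test sidedness (default two-sided).
#' @return object of class `direction_summary`: list with `counts` (named:
#'   proximal, distal, anterior, posterior, stuck), `n_total`, `fractions`,
#'   `axial_fraction`, `axial_fraction_moving`, `distal_vs_proximal_p`
#'   (`NA` when no axial tracks), `significant` (p <= 0.05), `labels`
#'   (per-track).
#' @export
direction_summary <- function(tracks, stuck_eps = 0,
                              alternative = "two.sided") {
  trs <- split_tracks(tracks)
  if (length(trs) == 0) stop_param("no tracks to summarize")
  labels <- vapply(trs, classify_net_direction, character(1),
                   stuck_eps = stuck_eps)
  cats <- c("proximal", "distal", "anterior", "posterior", "stuck")
  counts <- vapply(cats, function(k) sum(labels == k), integer(1))
  n <- length(labels)
  nd <- counts[["distal"]]; np <- counts[["proximal"]]
  p <- if (nd + np == 0) NA_real_ else
    stats::binom.test(nd, nd + np, 0.5, alternative = alternative)$p.value
  structure(
    list(counts = counts, n_total = n, fractions = counts / n,
         axial_fraction = (nd + np) / n,
         axial_fraction_moving = if (n > counts[["stuck"]])
           (nd + np) / (n - counts[["stuck"]]) else NA_real_,
         distal_vs_proximal_p = p,
         significant = isTRUE(!is.na(p) && p <= 0.05),
         labels = labels),
    class = "direction_summary")
}

#' @export
print.direction_summary <- function(x, ...) {
  cat(sprintf("direction_summary: n = %d\n", x$n_total))
  print(x$counts)
  cat(sprintf("axial fraction = %.3f (%.3f among moving)\n",
              x$axial_fraction, x$axial_fraction_moving))
  cat(sprintf("distal vs proximal binomial p = %.4g%s\n",
              x$distal_vs_proximal_p,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Motion-mode classification: transcytotic vs wandering
#'
#' Straightness is the net displacement divided by the path length; the
#' pause fraction is the share of consecutive steps at most `stuck_eps`.
#' A non-stuck track is *transcytotic* (linear, processive) iff
#' `straightness >= straightness_min` and
#' `pause fraction <= pause_frac_max`; otherwise *wandering*.
#'
#' @param track data.frame of one track's frames.
#' @param straightness_min default 0.8.
#' @param pause_frac_max default 0.2.
#' @param stuck_eps step threshold counting as a pause.
#' @return `"transcytotic"`, `"wandering"`, or `"not_classifiable"` (stuck
#'   or fewer than 3 frames).
#' @export
classify_motion_mode <- function(track, straightness_min = 0.8,
                                 pause_frac_max = 0.2, stuck_eps = 0) {
  tr <- track[order(track$frame), , drop = FALSE]
  if (nrow(tr) < 3) return("not_classifiable")
  steps <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  path <- sum(steps)
  if (path <= stuck_eps * length(steps) || all(steps <= stuck_eps))
    return("not_classifiable")
  net <- sqrt((tr$x[nrow(tr)] - tr$x[1])^2 + (tr$y[nrow(tr)] - tr$y[1])^2)
  straightness <- net / path
  pause_frac <- mean(steps <= stuck_eps)
  if (straightness >= straightness_min && pause_frac <= pause_frac_max)
    "transcytotic" else "wandering"
}

#' Transcytosis ratio table by group
#'
#' Share of transcytotic tracks among classifiable tracks, per group (e.g.
#' pupal age in hours after puparium formation).
#'
#' @param tracks track data.frame.
#' @param group per-track grouping vector named or ordered by `track_id`, or
#'   the name of a column in `tracks`.
#' @param ... passed to [classify_motion_mode()].
#' @return data.frame with `group`, `n_classifiable`, `n_transcytotic`,
#'   `ratio`.
#' @export
transcytosis_ratio_table <- function(tracks, group, ...) {
  trs <- split_tracks(tracks)
  modes <- vapply(trs, classify_motion_mode, character(1), ...)
  if (is.character(group) && length(group) == 1 && group %in% names(tracks)) {
    g <- vapply(trs, function(tr) as.character(tr[[group]][1]), character(1))
  } else {
    g <- as.character(group)
    if (length(g) != length(trs))
      stop_param("group must name a column or have one value per track")
  }
  ok <- modes != "not_classifiable"
  out <- do.call(rbind, lapply(split(modes[ok], g[ok]), function(m) {
    data.frame(n_classifiable = length(m),
               n_transcytotic = sum(m == "transcytotic"),
               ratio = mean(m == "transcytotic"))
  }))
  out$group <- rownames(out)
  rownames(out) <- NULL
  out[, c("group", "n_classifiable", "n_transcytotic", "ratio")]
}
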