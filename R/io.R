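## Readers, writers and the config-driven pipeline runner.

#' Read a single- or multi-channel TIFF image
#'
#' @param path TIFF file path.
#' @return numeric matrix (single channel) or 3-D array `[y, x, channel]`,
#'   with attribute `pixel_size` when resolution metadata is present.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_param("image file not found: %s", path)
  img <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                  error = function(e)
                    stop_param("cannot read TIFF '%s': %s", path,
                               conditionMessage(e)))
  arr <- lapply(img, function(f) {
    if (length(dim(f)) > 3) stop_param("'%s': >=4-D images unsupported", path)
    f
  })
  out <- if (length(arr) == 1L) {
    a <- arr[[1]]
    if (length(dim(a)) == 3L && dim(a)[3] == 1L) a[, , 1] else a
  } else {
    simplify2array(lapply(arr, function(f)
      if (length(dim(f)) == 3L) f[, , 1] else f))
  }
  attributes(out) <- attributes(out)["dim"]
  res <- attr(img[[1]], "x.resolution")
  if (!is.null(res) && is.numeric(res) && res > 0)
    attr(out, "pixel_size") <- 1 / res
  out
}

#' Write an image (or list of channels) as TIFF
#'
#' Intensities are stored as 32-bit floats after scaling into `[0, 1]` when
#' needed; the scale factor is not retained, so round-trips are lossless
#' only for data already in `[0, 1]`.
#'
#' @param img matrix, 3-D array `[y, x, channel]`, or list of matrices.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_image <- function(img, path) {
  to_list <- function(x) {
    if (is.list(x)) return(x)
    if (length(dim(x)) == 3L)
      return(lapply(seq_len(dim(x)[3]), function(k) x[, , k]))
    list(x)
  }
  chans <- to_list(img)
  mx <- max(vapply(chans, max, numeric(1)), 1)
  chans <- lapply(chans, function(m) m / mx)
  tiff::writeTIFF(chans, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read vesicle tracks from CSV
#'
#' Validates the track table: required columns, no duplicate
#' `(track_id, frame)` pairs, strictly increasing `t_seconds` within each
#' track. Extra columns pass through. Rows are returned sorted by
#' `track_id` then `frame`.
#'
#' @param path CSV with columns `track_id, frame, t_seconds, x, y` (extra
#'   columns kept).
#' @return validated, sorted track data.frame.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop_param("track file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "t_seconds", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_param("'%s': missing column(s) %s", path, paste(miss, collapse = ", "))
  key <- paste(df$track_id, df$frame)
  if (anyDuplicated(key)) {
    row <- which(duplicated(key))[1]
    stop_param("'%s': duplicate (track_id, frame) at row %d", path, row)
  }
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  for (tr in split(seq_len(nrow(df)), df$track_id)) {
    tt <- df$t_seconds[tr]
    if (any(diff(tt) <= 0))
      stop_param("'%s': non-increasing t_seconds in track %s (row %d)",
                 path, df$track_id[tr[1]], tr[which(diff(tt) <= 0)[1] + 1])
  }
  rownames(df) <- NULL
  df
}

#' Write tracks to CSV
#' @param tracks track data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

write_metadata <- function(dir, stage, params, seed) {
  meta <- list(stage = stage, seed = seed, parameters = params,
               package = "wingpol",
               version = as.character(utils::packageVersion("wingpol")))
  jsonlite::write_json(meta, file.path(dir, paste0(stage, "_metadata.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run one pipeline stage from a configuration
#'
#' Executes a stage end to end: generate synthetic inputs, or quantify
#' existing inputs, writing outputs plus a metadata record (stage,
#' parameters, seed, package version) into the output directory. All
#' randomness flows from the config seed through [child_seeds()], so the
#' same configuration reproduces every output.
#'
#' Stages: `synth_tracks` (writes `tracks.csv`), `synth_fibers` (writes
#' `fibers.tif` and `fiber_truth.json`), `synth_pair` (writes `dots.tif`,
#' `membrane.tif`, `pair_truth.json`), `tracks` (direction summary JSON from
#' a track CSV), `orient` (orientation histogram JSON from a TIFF), `coloc`
#' (shift-correlation JSON from two TIFFs), `anchors` (anchoring statistics
#' JSON from angles or a traced-point CSV), `simulate` (polarity cell table
#' and per-column kinetics CSVs).
#'
#' @param config list (or path to a YAML file) with elements `stage`,
#'   `out_dir`, `seed` (default 1) and `params` (stage-specific arguments).
#' @return invisibly, a list of the stage's main results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stage <- config$stage
  if (is.null(stage)) stop_param("config must name a stage")
  out_dir <- config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed %||% 1L
  prm <- config$params %||% list()
  sd <- child_seeds(seed, 4)

  result <- switch(stage,
    synth_tracks = {
      tm <- do.call(make_track_mixture,
                    c(prm[setdiff(names(prm), "seed")], list(seed = sd[1])))
      write_tracks(tm$tracks, file.path(out_dir, "tracks.csv"))
      jsonlite::write_json(list(labels = tm$labels, p_distal = tm$p_distal),
                           file.path(out_dir, "tracks_truth.json"),
                           auto_unbox = TRUE, digits = NA)
      list(mixture = tm)
    },
    synth_fibers = {
      fi <- do.call(make_fiber_image,
                    c(prm[setdiff(names(prm), "seed")], list(seed = sd[1])))
      write_image(fi$image / max(fi$image), file.path(out_dir, "fibers.tif"))
      jsonlite::write_json(list(mu_deg = fi$mu_deg, kappa = fi$kappa,
                                fiber_angles = fi$fiber_angles),
                           file.path(out_dir, "fiber_truth.json"),
                           auto_unbox = TRUE, digits = NA)
      list(fibers = fi)
    },
    synth_pair = {
      grid_pr <- prm$grid %||% list(n_rows = 6, n_cols = 8)
      g <- hex_grid(grid_pr$n_rows, grid_pr$n_cols)
      pr <- do.call(make_dot_membrane_pair,
                    c(list(grid = g),
                      prm[setdiff(names(prm), c("seed", "grid"))],
                      list(seed = sd[1])))
      write_image(pr$dots / max(pr$dots), file.path(out_dir, "dots.tif"))
      write_image(pr$membrane / max(pr$membrane),
                  file.path(out_dir, "membrane.tif"))
      jsonlite::write_json(list(offset_px = pr$offset_px,
                                apothem_px = pr$apothem_px),
                           file.path(out_dir, "pair_truth.json"),
                           auto_unbox = TRUE, digits = NA)
      list(pair = pr)
    },
    tracks = {
      df <- filter_tracks(read_tracks(prm$input),
                          min_frames = prm$min_frames %||% 2)
      ds <- direction_summary(df, stuck_eps = prm$stuck_eps %||% 0)
      jsonlite::write_json(
        list(counts = as.list(ds$counts), n_total = ds$n_total,
             axial_fraction = ds$axial_fraction,
             axial_fraction_moving = ds$axial_fraction_moving,
             distal_vs_proximal_p = ds$distal_vs_proximal_p,
             significant = ds$significant,
             labels = as.list(ds$labels)),
        file.path(out_dir, "direction_summary.json"),
        auto_unbox = TRUE, digits = NA)
      list(summary = ds)
    },
    orient = {
      img <- read_image(prm$input)
      if (length(dim(img)) == 3L) img <- img[, , prm$channel %||% 1]
      of <- structure_tensor_orientation(img,
              sigma_grad = prm$sigma_grad %||% 1,
              sigma_window = prm$sigma_window %||% 4)
      oh <- orientation_histogram(of, n_bins = prm$bins %||% 36)
      if (!is.null(prm$axis_deg) && prm$axis_deg != 0)
        oh <- align_to_axis(oh, prm$axis_deg)
      co <- circular_order(oh)
      jsonlite::write_json(
        list(bins = oh$n_bins, width_deg = oh$bin_width,
             weights = oh$weights, mean_axial_deg = co$mean_deg,
             resultant_R = co$R, axis_offset_deg = oh$axis_offset_deg),
        file.path(out_dir, "hist.json"), auto_unbox = TRUE, digits = NA)
      list(histogram = oh)
    },
    coloc = {
      a <- read_image(prm$a); b <- read_image(prm$b)
      profile <- shift_correlation(a, b,
        axis = toupper(prm$axis %||% "PD"),
        max_shift = prm$max_shift %||% 20)
      jsonlite::write_json(
        list(shifts = profile$shifts, r = profile$r,
             A = profile$A, B = profile$B, asymmetry = profile$asymmetry),
        file.path(out_dir, "profile.json"), auto_unbox = TRUE, digits = NA)
      list(profile = profile)
    },
    anchors = {
      ang <- if (!is.null(prm$input))
        anchoring_angles_from_points(utils::read.csv(prm$input))
      else as.numeric(prm$angles_deg)
      st <- axial_bias_stats(ang)
      hh <- anchoring_histogram(ang, n_bins = prm$bins %||% 20)
      jsonlite::write_json(
        list(counts = hh$counts, bin_width = hh$bin_width,
             raw_R = st$raw$R, axial_R = st$axial$R,
             n_distal = st$n_distal, n_proximal = st$n_proximal,
             binomial_p = st$binomial_p),
        file.path(out_dir, "anchors.json"), auto_unbox = TRUE, digits = NA)
      list(stats = st, histogram = hh)
    },
    simulate = {
      g <- hex_grid(prm$n_rows %||% 6, prm$n_cols %||% 30)
      ds <- make_gradient(prm$ds_kind %||% "linear", g$n_cols)
      sim <- pcp_pipeline(g, ds,
                          fj = prm$fj %||% 0.5,
                          mt_mode = prm$mt_mode %||% "coupled",
                          t_end = prm$t_end %||% 300)
      ro <- render_polarity(sim)
      utils::write.csv(ro$cells, file.path(out_dir, "cells.csv"),
                       row.names = FALSE)
      kin <- polarization_kinetics(sim)
      utils::write.csv(
        data.frame(time = kin$times, kin$mean_P, check.names = FALSE),
        file.path(out_dir, "kinetics.csv"), row.names = FALSE)
      list(sim = sim)
    },
    stop_param("unknown stage '%s'", stage))

  write_metadata(out_dir, stage, prm, seed)
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
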