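mk_track <- function(x, y, id = 1, apical = TRUE) {
  n <- length(x)
  data.frame(track_id = id, frame = seq_len(n), t_seconds = (seq_len(n) - 1) * 5,
             x = x, y = y, apical = apical)
}

test_that("track filtering enforces consecutive apical visibility", {
  one <- mk_track(1, 1)
  expect_equal(nrow(filter_tracks(one)), 0)
  two <- mk_track(c(1, 2), c(0, 0))
  expect_equal(nrow(filter_tracks(two)), 2)
  # 5 frames but only one apical -> dropped under require_apical
  spotty <- mk_track(1:5, rep(0, 5), apical = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(nrow(filter_tracks(spotty)), 0)
  expect_equal(nrow(filter_tracks(spotty, require_apical = FALSE)), 5)
  # longest consecutive apical run is kept
  runs <- mk_track(1:7, rep(0, 7),
                   apical = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE))
  kept <- filter_tracks(runs)
  expect_equal(kept$frame, 3:5)
})

test_that("net-direction classification matches the brute-force oracle", {
  for (vx in -2:2) for (vy in -2:2) {
    tr <- mk_track(c(0, vx / 2, vx), c(0, vy / 2, vy))
    got <- classify_net_direction(tr)
    want <- oracle_direction(vx, vy)
    if (want == "zero") {
      # zero net vector without wiggle is stuck
      expect_equal(got, "stuck")
    } else {
      expect_equal(got, want, label = sprintf("v=(%d,%d): %s", vx, vy, got))
    }
  }
  # zero displacement every frame -> stuck
  expect_equal(classify_net_direction(mk_track(rep(2, 4), rep(3, 4))), "stuck")
  # super-eps wiggling with zero net vector -> axial tie rule (distal)
  wig <- mk_track(c(0, 3, 0), c(0, 0, 0))
  expect_equal(classify_net_direction(wig), "distal")
})

test_that("direction summary counts, fractions and the binomial test", {
  trs <- do.call(rbind, c(
    lapply(1:25, function(i) mk_track(c(0, 3), c(0, 0), id = i)),
    lapply(26:50, function(i) mk_track(c(0, -3), c(0, 0), id = i)),
    lapply(51:60, function(i) mk_track(c(0, 0), c(0, 0), id = i))))
  ds <- direction_summary(trs)
  expect_equal(unname(ds$counts[c("distal", "proximal", "stuck")]),
               c(25L, 25L, 10L))
  expect_equal(ds$n_total, 60)
  expect_equal(ds$axial_fraction, 50 / 60)
  expect_equal(ds$axial_fraction_moving, 1)
  expect_equal(ds$distal_vs_proximal_p, 1)
  expect_false(ds$significant)
})

test_that("flipping the x axis swaps proximal/distal, keeps the p-value", {
  tm <- make_track_mixture(120, 0.7, 0.2, 0.1, p_distal = 0.8, seed = 13)
  tf <- filter_tracks(tm$tracks)
  ds1 <- direction_summary(tf)
  tf2 <- tf
  tf2$x <- -tf2$x
  ds2 <- direction_summary(tf2)
  expect_equal(unname(ds1$counts[["distal"]]), unname(ds2$counts[["proximal"]]))
  expect_equal(unname(ds1$counts[["anterior"]]), unname(ds2$counts[["anterior"]]))
  expect_equal(ds1$distal_vs_proximal_p, ds2$distal_vs_proximal_p)
})

test_that("binomial p matches enumeration for all n <= 30", {
  for (n in c(5, 12, 30)) {
    for (x in c(0, floor(n / 3), n)) {
      trs <- do.call(rbind, c(
        if (x > 0) lapply(seq_len(x), function(i) mk_track(c(0, 2), c(0, 0), id = i)),
        if (n - x > 0) lapply(x + seq_len(n - x),
                              function(i) mk_track(c(0, -2), c(0, 0), id = i))))
      ds <- direction_summary(trs)
      expect_equal(ds$distal_vs_proximal_p, oracle_binom_p(x, n),
                   tolerance = 1e-12)
    }
  }
})

test_that("motion-mode classification separates generator modes", {
  # perfectly straight constant velocity -> transcytotic
  expect_equal(classify_motion_mode(mk_track(seq(0, 10, 2), rep(0, 6))),
               "transcytotic")
  expect_equal(classify_motion_mode(mk_track(c(0, 1), c(0, 0))),
               "not_classifiable")
  tm <- make_track_mixture(300, 0.5, 0.5, 0, seed = 17)
  tf <- filter_tracks(tm$tracks)
  modes <- vapply(split(tf, tf$track_id), classify_motion_mode, character(1))
  truth <- tm$labels
  expect_gte(mean(modes[truth == "wandering"] == "wandering"), 0.9)
  expect_gte(mean(modes[truth == "transcytotic"] == "transcytotic"), 0.9)
})

test_that("per-group transcytosis ratio table aggregates by age", {
  tm <- make_track_mixture(60, 0.5, 0.5, 0, seed = 23)
  tr <- tm$tracks
  tr$age_hapf <- ifelse(tr$track_id <= 30, "15h", "24h")
  tab <- transcytosis_ratio_table(tr, "age_hapf")
  expect_equal(sort(tab$group), c("15h", "24h"))
  expect_equal(sum(tab$n_classifiable), 60)
  expect_true(all(tab$ratio >= 0 & tab$ratio <= 1))
})

test_that("every filtered track gets exactly one category", {
  tm <- make_track_mixture(80, 0.4, 0.4, 0.2, seed = 31)
  tf <- filter_tracks(tm$tracks)
  ds <- direction_summary(tf)
  expect_equal(sum(ds$counts), length(unique(tf$track_id)))
  expect_true(all(ds$labels %in% c("proximal", "distal", "anterior",
                                   "posterior", "stuck")))
})
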