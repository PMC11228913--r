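test_that("nearest-neighbour linking follows the centroid distance", {
  prev <- make_obs(0, 1, 1000, z = 10, y = 10, x = 10)
  nxt <- make_obs(1, 1, 950, z = 10, y = 10, x = 11)
  lk <- link_frames(prev, nxt)
  expect_equal(lk$prev_label, 1L)
  expect_equal(lk$distance, 1)

  # empty inputs
  expect_equal(nrow(link_frames(prev[0, ], nxt[0, ])), 0L)
  lk2 <- link_frames(prev[0, ], nxt)
  expect_true(is.na(lk2$prev_label))
})

test_that("many-to-one candidate links agree with the all-pairs distance matrix", {
  prev <- dplyr::bind_rows(
    make_obs(0, 1, 1000, z = 10, y = 10, x = 10),
    make_obs(0, 2, 800, z = 10, y = 10, x = 60))
  nxt <- dplyr::bind_rows(
    make_obs(1, 1, 500, z = 10, y = 8, x = 12),
    make_obs(1, 2, 450, z = 10, y = 12, x = 9),
    make_obs(1, 3, 780, z = 10, y = 10, x = 59))
  lk <- link_frames(prev, nxt)
  # brute force: distance matrix, nearest predecessor per next observation
  for (j in seq_len(nrow(nxt))) {
    d <- sqrt((prev$z - nxt$z[j])^2 + (prev$y - nxt$y[j])^2 + (prev$x - nxt$x[j])^2)
    expect_equal(lk$prev_label[j], prev$label[which.min(d)])
  }
  # both fragments nearest to predecessor 1: breakup candidate encoded
  expect_equal(lk$prev_label[1:2], c(1L, 1L))
})

test_that("sequence matching survives a position swap via volume consistency", {
  # A (large) moves slightly; B (small) moves exactly onto A's old position
  obs <- dplyr::bind_rows(
    make_obs(0, 1, 8000, z = 10, y = 10, x = 10),  # A
    make_obs(0, 2, 600, z = 10, y = 10, x = 24),   # B
    make_obs(1, 1, 7800, z = 12, y = 12, x = 13),  # A moved
    make_obs(1, 2, 580, z = 10, y = 10, x = 10),   # B sits on A's old spot
    make_obs(2, 1, 7500, z = 12, y = 12, x = 13),
    make_obs(2, 2, 540, z = 10, y = 10, x = 10),
    make_obs(3, 1, 7100, z = 12, y = 12, x = 13),
    make_obs(3, 2, 500, z = 10, y = 10, x = 10))
  tracks <- match_sequences(obs)
  vols <- tracks |>
    dplyr::arrange(.data$track_id, .data$frame_index) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(v = list(voxel_count), .groups = "drop")
  expect_equal(vols$v[[1]], c(8000L, 7800L, 7500L, 7100L))  # A follows A
  expect_equal(vols$v[[2]], c(600L, 580L, 540L, 500L))      # B follows B
})

test_that("unambiguous series reduce to nearest-neighbour chaining", {
  obs <- dplyr::bind_rows(lapply(0:4, function(f) {
    dplyr::bind_rows(
      make_obs(f, 1, 1000 - 50 * f, z = 20, y = 20, x = 20),
      make_obs(f, 2, 700 - 30 * f, z = 60, y = 60, x = 60))
  }))
  tracks <- match_sequences(obs)
  expect_equal(dplyr::n_distinct(tracks$track_id), 2L)
  expect_equal(nrow(tracks), 10L)
  # each observation in exactly one track (partition)
  expect_equal(dplyr::count(tracks, frame_index, label) |> nrow(), 10L)
})

test_that("breakup creates two child tracks with the mother's lineage", {
  obs <- dplyr::bind_rows(
    make_obs(0, 1, 4000, z = 30, y = 30, x = 30),
    make_obs(1, 1, 3600, z = 30, y = 30, x = 30),
    make_obs(2, 1, 1600, z = 30, y = 25, x = 30),  # fragment 1
    make_obs(2, 2, 1500, z = 30, y = 35, x = 30),  # fragment 2
    make_obs(3, 1, 1400, z = 30, y = 25, x = 30),
    make_obs(3, 2, 1300, z = 30, y = 35, x = 30))
  tracks <- match_sequences(obs)
  ids <- dplyr::distinct(tracks, track_id, mother_id)
  expect_equal(nrow(ids), 3L)
  mother <- ids$track_id[is.na(ids$mother_id)]
  children <- ids[!is.na(ids$mother_id), ]
  expect_equal(nrow(children), 2L)
  expect_true(all(children$mother_id == mother))
  # fragments' summed volume below the mother's: consistent with breakup
  expect_lte(1600 + 1500, 3600)
})

test_that("pass 1 removes growth: hand-traced fixtures", {
  p <- tracking_params(growth_tolerance = 0.02)
  # growth at step 2, prefix of 2 < 4 -> rejected with reason growth
  t1 <- make_track(c(100, 90, 95, 80)); t1$track_id <- 1L; t1$mother_id <- NA_integer_
  out1 <- filter_pass1(as_tracks_for_test(t1), p)
  expect_equal(nrow(out1), 0L)
  expect_equal(rejections(out1)$reason, "growth")

  # strictly decreasing: untouched
  t2 <- make_track(c(100, 90, 80, 70, 60)); t2$track_id <- 1L; t2$mother_id <- NA_integer_
  expect_equal(nrow(filter_pass1(as_tracks_for_test(t2), p)), 5L)

  # growth within tolerance: kept whole
  t3 <- make_track(c(100, 101, 99, 98, 97)); t3$track_id <- 1L; t3$mother_id <- NA_integer_
  expect_equal(nrow(filter_pass1(as_tracks_for_test(t3), p)), 5L)
})

test_that("pass 2 breaks improbable jumps: hand-traced fixtures", {
  p <- tracking_params(jump_volume_fraction = 0.5, sphericity_jump = 0.3)
  # 95 -> 20 is a 79% drop: track broken, both pieces too short
  t1 <- make_track(c(100, 95, 20, 18)); t1$track_id <- 1L; t1$mother_id <- NA_integer_
  out1 <- filter_pass2(as_tracks_for_test(t1), p)
  expect_equal(nrow(out1), 0L)
  expect_true(all(rejections(out1)$reason == "jump"))

  # gentle decay: all steps well under the jump threshold
  t2 <- make_track(c(100, 90, 81, 73, 66)); t2$track_id <- 1L; t2$mother_id <- NA_integer_
  expect_equal(nrow(filter_pass2(as_tracks_for_test(t2), p)), 5L)

  # sphericity jump breaks the track even with smooth volumes
  t3 <- make_track(c(100, 98, 96, 94), roundness = c(0.8, 0.79, 0.3, 0.3))
  t3$track_id <- 1L; t3$mother_id <- NA_integer_
  out3 <- filter_pass2(as_tracks_for_test(t3), p)
  expect_equal(nrow(out3), 0L)
  expect_true(all(rejections(out3)$reason == "jump"))
})

test_that("accepted tracks never grow beyond tolerance in V or A", {
  set.seed(14)
  # random noisy tracks through the full filter chain
  obs <- dplyr::bind_rows(lapply(0:7, function(f) {
    dplyr::bind_rows(lapply(1:5, function(l) {
      make_obs(f, l, round(2000 * 0.85^f * runif(1, 0.9, 1.1)),
               z = 10 * l, y = 10 * l, x = 40 * l)
    }))
  }))
  p <- tracking_params()
  out <- track_crystals(obs, p)
  if (nrow(out) > 0) {
    chk <- out |>
      dplyr::arrange(.data$track_id, .data$frame_index) |>
      dplyr::group_by(.data$track_id) |>
      dplyr::summarise(
        ok = all(volume_cm3[-1] <=
                   volume_cm3[-dplyr::n()] * (1 + p$growth_tolerance)),
        .groups = "drop")
    expect_true(all(chk$ok))
  }
  expect_gt(nrow(out), 0L)  # the fixture is designed to keep some tracks
})

test_that("minimum-length rule and per-class data-point accounting", {
  p <- tracking_params()
  t1 <- make_track(c(100, 90, 80))  # 3 observations: excluded
  t1$track_id <- 1L; t1$mother_id <- NA_integer_
  out <- finalize_tracks(as_tracks_for_test(t1), p)
  expect_equal(nrow(out), 0L)
  expect_equal(rejections(out)$reason, "short")

  # data points per crystal: 22 crystals x 121 points -> 5.5,
  # 64 x 379 -> 5.9, exercising the population accounting arithmetic
  mk_class_tracks <- function(n_tracks, n_points, diam_um, id0) {
    base <- n_points %/% n_tracks
    extra <- n_points - base * n_tracks
    lens <- c(rep(base + 1L, extra), rep(base, n_tracks - extra))
    dplyr::bind_rows(lapply(seq_len(n_tracks), function(i) {
      tr <- make_track(seq(1000, by = -10, length.out = lens[i]))
      tr$track_id <- id0 + i
      tr$mother_id <- NA_integer_
      tr$equiv_diam_cm <- diam_um * 1e-4
      tr
    }))
  }
  tracks <- dplyr::bind_rows(
    mk_class_tracks(22, 121, 210, 0L),
    mk_class_tracks(106, 587, 350, 100L),
    mk_class_tracks(64, 379, 450, 300L))
  summ <- track_summary(tracks, size_classes())
  expect_equal(summ$tracked_crystals, c(22L, 106L, 64L))
  expect_equal(summ$data_points, c(121L, 587L, 379L))
  expect_equal(summ$data_points_per_crystal, c(5.5, 5.5, 5.9))
})

test_that("tracking is deterministic", {
  set.seed(33)
  obs <- dplyr::bind_rows(lapply(0:5, function(f) {
    dplyr::bind_rows(lapply(1:6, function(l) {
      make_obs(f, l, round(3000 * 0.9^f + 10 * l), z = 15 * l, y = 12 * l, x = 30 * l)
    }))
  }))
  a <- track_crystals(obs)
  b <- track_crystals(obs)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
})
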