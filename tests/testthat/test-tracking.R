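test_that("well-separated stationary particles give one track each", {
  det <- data.frame(frame = rep(0:9, each = 2),
                    x_um = rep(c(1, 6), 10), y_um = rep(c(1, 1), 10))
  tracks <- link_detections(det)
  expect_equal(n_tracks(tracks), 2L)
  expect_true(all(table(tracks$track_id) == 10))
})

test_that("a missing detection is bridged by gap closing", {
  det <- data.frame(frame = 0:9, x_um = 0.05 * (0:9), y_um = 0)
  det <- det[det$frame != 5, ]
  tracks <- link_detections(det)
  expect_equal(n_tracks(tracks), 1L)
  expect_equal(sort(tracks$frame), c(0:4, 6:9))
})

test_that("a gap beyond max_gap is not bridged", {
  det <- data.frame(frame = 0:9, x_um = 0.05 * (0:9), y_um = 0)
  det <- det[!det$frame %in% 4:6, ]   # 3 skipped frames > max_gap = 2
  tracks <- link_detections(det, max_gap = 2)
  expect_equal(n_tracks(tracks), 2L)
})

test_that("a jump beyond the linking distance terminates the track", {
  det <- data.frame(frame = 0:5, x_um = c(0, 0.1, 0.2, 2.2, 2.3, 2.4), y_um = 0)
  tracks <- link_detections(det, max_link_dist = 1.5, max_gap = 0)
  expect_equal(n_tracks(tracks), 2L)
  lens <- as.vector(table(tracks$track_id))
  expect_equal(sort(lens), c(3L, 3L))
})

test_that("empty input yields an empty track set, not an error", {
  empty <- data.frame(frame = integer(0), x_um = numeric(0), y_um = numeric(0))
  tracks <- link_detections(empty)
  expect_s3_class(tracks, "trajectory_set")
  expect_equal(nrow(tracks), 0L)
  expect_error(link_detections(empty, max_link_dist = -1), ">= 0")
})

test_that("every detection is assigned to exactly one track", {
  sim <- sparse_sim(4)
  det <- render_detections(sim$tracks, 0.01, 0.1, seed = 5)
  tracks <- link_detections(det)
  expect_equal(nrow(tracks), nrow(det))   # partition property
  expect_false(any(duplicated(tracks[, c("track_id", "frame")])))
})

test_that("the track partition is invariant to detection row order", {
  sim <- sparse_sim(5)
  det <- render_detections(sim$tracks, 0, 0, seed = 6)
  tracks_a <- link_detections(det)
  set.seed(77)
  det_shuf <- det[sample.int(nrow(det)), , drop = FALSE]
  tracks_b <- link_detections(det_shuf)
  expect_identical(as.data.frame(tracks_a), as.data.frame(tracks_b))
})

test_that("sparse noiseless simulations are recovered exactly", {
  for (seed in c(2, 3, 5)) {
    sim <- sparse_sim(seed)
    # the oracle's premise: identities are only recoverable when particles
    # never approach within the assignment-ambiguity scale
    expect_gt(min_pair_separation(sim$tracks), 1)
    det <- render_detections(sim$tracks, 0, 0, seed = seed + 50)
    expect_true(partition_matches_truth(link_detections(det), det))
  }
})

test_that("bridged tracks still match ground truth after deleting a frame", {
  for (seed in c(2, 3, 5)) {
    sim <- sparse_sim(seed)
    det <- render_detections(sim$tracks, 0, 0, seed = seed + 60)
    det_gap <- det[det$frame != 5, , drop = FALSE]
    tracks <- link_detections(det_gap)
    expect_true(partition_matches_truth(tracks, det_gap))
    expect_equal(n_tracks(tracks), n_tracks(sim$tracks))
  }
})

test_that("filter_tracks keeps tracks at or above the length threshold", {
  pts <- rbind(line_track(1, 1), line_track(2, 2), line_track(3, 5))
  tracks <- trajectory_set(pts, 0.02)
  expect_equal(n_tracks(suppressMessages(filter_tracks(tracks, 1))), 3L)
  expect_equal(n_tracks(suppressMessages(filter_tracks(tracks, 3))), 1L)
  expect_warning(suppressMessages(filter_tracks(tracks, 10)), "retained")
  expect_error(filter_tracks(tracks, 0), ">= 1")
})

test_that("TrackMate spot exports are imported with unit conversion", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    "LABEL,ID,TRACK_ID,POSITION_X,POSITION_Y,FRAME",
    "Label,Spot ID,Track ID,X,Y,Frame",          # TrackMate's extra header rows
    " , , ,(um),(um), ",
    "ID1,1,0,10.0,20.0,0",
    "ID2,2,0,10.5,20.0,1",
    "ID3,3,1,40.0,5.0,0"), f)
  tracks <- read_trackmate_csv(f, pixel_size_um = 0.1)
  expect_equal(n_tracks(tracks), 2L)
  expect_equal(tracks$x_um[tracks$track_id == 0 & tracks$frame == 0], 1.0)
  expect_equal(max(tracks$y_um), 2.0)
})
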