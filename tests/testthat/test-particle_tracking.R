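px <- 0.16

test_that("LoG detection localises isolated spots to sub-pixel accuracy", {
  f <- synapseflow:::render_spots(256, 256, 20.37 / px, 10.23 / px,
                                  (1 / 2.355) / px)
  st <- image_stack(f, px, 0.1)
  d <- detect_blobs(st, diameter = 1.0, quality_threshold = 0.1)
  expect_equal(nrow(d), 1)
  expect_lt(sqrt((d$x_um - 10.23)^2 + (d$y_um - 20.37)^2), 0.05)
})

test_that("detection trivia: blank frames, two spots, resolvability guard", {
  blank <- image_stack(matrix(0.001, 64, 64) + 0, px, 0.1)
  expect_equal(nrow(detect_blobs(blank, 1, 0.1)), 0)
  f2 <- synapseflow:::render_spots(256, 256, c(100, 100 + 5 / px),
                                   c(100, 100), (1 / 2.355) / px)
  expect_equal(nrow(detect_blobs(image_stack(f2, px, 0.1), 1, 0.1)), 2)
  expect_error(detect_blobs(blank, diameter = 0.2), "resolvable")
})

test_that("a single moving spot links into one full track", {
  det <- data.frame(frame = 1:30, x_um = 0.3 * (0:29), y_um = 5)
  tr <- link_tracks(det, link_config(), frame_interval = 1)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 30)
  expect_false(any(tr$gap_before))
})

test_that("a 2-frame disappearance within the gap gate is closed", {
  det <- data.frame(frame = 1:30, x_um = 0.15 * (0:29), y_um = 5)
  det <- det[!(det$frame %in% c(10, 11)), ]   # 0.45 um jump over the gap
  tr <- link_tracks(det, link_config(), frame_interval = 1)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(sum(tr$gap_before), 1)
  # a 3-frame disappearance exceeds max_gap_frames = 2 and stays split
  det3 <- data.frame(frame = 1:30, x_um = 0.1 * (0:29), y_um = 5)
  det3 <- det3[!(det3$frame %in% c(10, 11, 12)), ]
  tr3 <- link_tracks(det3, link_config(), frame_interval = 1)
  expect_equal(length(unique(tr3$track_id)), 2)
})

test_that("tracks shorter than min_duration are excluded", {
  # 16 frames at 0.1 s span 1.5 s < 2 s
  det <- data.frame(frame = 1:16, x_um = 0.05 * (1:16), y_um = 0)
  expect_equal(nrow(link_tracks(det, link_config(min_duration = 2),
                                frame_interval = 0.1)), 0)
  # 21 frames span exactly 2.0 s and are kept
  det2 <- data.frame(frame = 1:21, x_um = 0.05 * (1:21), y_um = 0)
  expect_equal(length(unique(link_tracks(det2, link_config(min_duration = 2),
                                         frame_interval = 0.1)$track_id)), 1)
})

test_that("track count is monotone in min_duration and max_gap_frames", {
  set.seed(10)
  sim <- simulate_tracks(n_tracks = 15, n_points = 40, frame_interval = 0.1,
                         model = "brownian", D = 0.02, seed = 10)
  det <- sim$tracks[, c("frame", "x_um", "y_um")]
  det <- det[runif(nrow(det)) > 0.1, ]        # random 10% missed detections
  counts_dur <- vapply(c(0, 1, 2, 3), function(md)
    length(unique(link_tracks(det, link_config(min_duration = md),
                              frame_interval = 0.1)$track_id)),
    numeric(1))
  expect_true(all(diff(counts_dur) <= 0))
  counts_gap <- vapply(c(0L, 1L, 2L, 4L), function(gf)
    length(unique(link_tracks(det, link_config(max_gap_frames = gf,
                                               min_duration = 0),
                              frame_interval = 0.1)$track_id)),
    numeric(1))
  expect_true(all(diff(counts_gap) <= 0))   # more gap closing, fewer tracks
})

test_that("well-separated noiseless scenes are recovered exactly", {
  # 5 spots on a coarse grid (>= 5 x max_link_distance apart), drifting
  set.seed(11)
  n_sp <- 5
  start_x <- seq(5, 25, length.out = n_sp)
  start_y <- rep(c(8, 20), length.out = n_sp)
  truth <- do.call(rbind, lapply(seq_len(n_sp), function(k) {
    data.frame(track_id = k, frame = 1:20,
               t_s = (0:19) * 0.1,
               x_um = start_x[k] + 0.03 * (0:19),
               y_um = start_y[k] + 0.02 * (0:19) * (-1)^k)
  }))
  st <- render_track_movie(truth, size_px = 220, pixel_size = px,
                           frame_interval = 0.1)
  det <- detect_blobs(st, diameter = 1.0, quality_threshold = 0.1)
  tr <- link_tracks(det, link_config(min_duration = 1), frame_interval = 0.1)
  expect_equal(length(unique(tr$track_id)), n_sp)
  expect_true(all(table(tr$track_id) == 20))
  # per-point position error < 0.1 um (match tracks by starting point)
  for (tid in unique(tr$track_id)) {
    sub <- tr[tr$track_id == tid, ]
    sub <- sub[order(sub$frame), ]
    k <- which.min((start_x - sub$x_um[1])^2 + (start_y - sub$y_um[1])^2)
    tru <- truth[truth$track_id == k, ]
    expect_lt(max(sqrt((sub$x_um - tru$x_um)^2 + (sub$y_um - tru$y_um)^2)),
              0.1)
  }
})

test_that("instantaneous speeds follow the inter-frame definition", {
  tr <- data.frame(track_id = 1, frame = 1:10, t_s = (0:9) * 1,
                   x_um = 0.13 * (0:9), y_um = 2)
  expect_equal(instantaneous_speeds(tr), rep(0.13, 9))
  trs <- tr; trs$x_um <- 0.5
  expect_equal(instantaneous_speeds(trs), rep(0, 9))
  # removing frames 5-6 kills the pairs (4,5), (5,6), (6,7): 9 - 3 = 6
  trg <- tr[tr$frame != 5 & tr$frame != 6, ]
  expect_length(instantaneous_speeds(trg), 6)
  expect_error(instantaneous_speeds(tr[1, ]), "fewer than 2")
})

test_that("directed-motion speed is recovered within 5% (noiseless)", {
  sim <- simulate_tracks(n_tracks = 10, n_points = 30, frame_interval = 0.1,
                         model = "directed", D = 0, speed_um_s = 0.2,
                         seed = 12)
  sp <- unlist(lapply(split_tracks(sim$tracks), instantaneous_speeds))
  expect_lt(abs(stats::median(sp) - 0.2) / 0.2, 0.05)
})
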