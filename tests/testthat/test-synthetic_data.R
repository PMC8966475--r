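test_that("every generator is bit-reproducible under a fixed seed", {
  a <- generate_speckle_movie(size_px = 32, n_frames = 6, seed = 42)
  b <- generate_speckle_movie(size_px = 32, n_frames = 6, seed = 42)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_false(identical(
    a$stack$frames,
    generate_speckle_movie(size_px = 32, n_frames = 6, seed = 43)$stack$frames))
  t1 <- simulate_tracks(n_tracks = 3, n_points = 10, seed = 5)
  t2 <- simulate_tracks(n_tracks = 3, n_points = 10, seed = 5)
  expect_identical(t1$tracks, t2$tracks)
  s1 <- generate_spreading_movie(size_px = 64, A0_um2 = 80, duration_s = 50,
                                 seed = 7)
  s2 <- generate_spreading_movie(size_px = 64, A0_um2 = 80, duration_s = 50,
                                 seed = 7)
  expect_identical(s1$stack$frames, s2$stack$frames)
  g1 <- generate_granule_scene(seed = 9, noise_sd = 0.01)
  g2 <- generate_granule_scene(seed = 9, noise_sd = 0.01)
  expect_identical(g1$frame, g2$frame)
  f1 <- generate_tfm_scene(size_px = 96, seed = 11)
  f2 <- generate_tfm_scene(size_px = 96, seed = 11)
  expect_identical(f1$reference, f2$reference)
  expect_identical(f1$deformed, f2$deformed)
})

test_that("speckle generator enforces its guards", {
  expect_error(generate_speckle_movie(density = 0.005), "density")
  # aliasing guard: per-frame displacement must stay below subregion/4
  expect_error(generate_speckle_movie(speed_um_min = 30, frame_interval = 5),
               "aliasing")
  # zero flow leaves emitters static: frames identical up to noise
  g <- generate_speckle_movie(size_px = 32, n_frames = 4, flow = "none",
                              noise_sd = 0, seed = 1)
  expect_equal(g$stack$frames[, , 1], g$stack$frames[, , 4])
})

test_that("track simulation matches its stated motion models", {
  # deterministic limit: directed with D = 0 is exactly linear
  s <- simulate_tracks(n_tracks = 2, n_points = 20, frame_interval = 0.5,
                       model = "directed", D = 0, speed_um_s = 0.2,
                       direction_deg = 0, seed = 3)
  tr <- split_tracks(s$tracks)[[1]]
  expect_equal(diff(tr$x_um), rep(0.1, 19), tolerance = 1e-12)
  expect_equal(diff(tr$y_um), rep(0, 19), tolerance = 1e-12)
  # Brownian ensemble slope ~ 4D
  sb <- simulate_tracks(n_tracks = 200, n_points = 60, frame_interval = 1,
                        model = "brownian", D = 0.05, seed = 7)
  em <- ensemble_msd(sb$tracks, frame_interval = 1)
  slope <- sum(em$msd[1:15] * em$lags[1:15]) / sum(em$lags[1:15]^2)
  expect_lt(abs(slope - 4 * 0.05) / (4 * 0.05), 0.10)
  # confined: long-lag MSD plateaus at ~ L^2/3 (2D reflected diffusion),
  # and never exceeds the box diagonal bound 2 L^2
  sc <- simulate_tracks(n_tracks = 100, n_points = 300,
                        frame_interval = 0.1, model = "confined",
                        D = 0.05, box_um = 1, seed = 8)
  emc <- ensemble_msd(sc$tracks, frame_interval = 0.1)
  plateau <- mean(emc$msd[emc$lags > 10 & emc$lags < 25])
  expect_lt(abs(plateau - 1 / 3) / (1 / 3), 0.15)
  expect_true(all(emc$msd <= 2))
})

test_that("spreading movie follows the tanh law analytically", {
  g <- generate_spreading_movie(A0_um2 = 200, alpha = 0.02,
                                duration_s = 400, size_px = 96,
                                pixel_size = 0.25, seed = 2)
  # t -> large: area -> A0
  expect_lt(abs(utils::tail(g$truth$areas_um2, 1) - 200) / 200, 0.01)
  # doubling alpha halves the time to reach tanh(1) = 0.7616 of A0
  t76 <- function(alpha) {
    tt <- seq(0, 400, by = 0.5)
    tt[which(200 * tanh(alpha * tt) >= 200 * tanh(1))[1]]
  }
  expect_equal(t76(0.04) / t76(0.02), 0.5, tolerance = 0.02)
})

test_that("granule scene flags clumps and honours sub-threshold controls", {
  gr <- data.frame(radial_pos = c(0.3, 0.32, 0.8),
                   angle_deg = c(0, 2, 180),
                   radius_px = 3, intensity = 1)
  sc <- generate_granule_scene(granules = gr, seed = 4)
  expect_true(all(sc$truth$clumped[1:2]))
  expect_false(sc$truth$clumped[3])
  # overlapping pair is detected as one component -> 2 total
  gs <- binarize_granules(sc$frame, sc$mask)
  expect_equal(nrow(gs$components), 2)
  # a sub-threshold granule is absent (negative control)
  gr2 <- data.frame(radial_pos = c(0.3, 0.7), angle_deg = c(0, 180),
                    radius_px = 3, intensity = c(1, 0.05))
  sc2 <- generate_granule_scene(granules = gr2, seed = 5, bg_in = 0.3)
  gs2 <- binarize_granules(sc2$frame, sc2$mask)
  expect_equal(nrow(gs2$components), 1)
})

test_that("TFM scene stays in the recoverable displacement regime", {
  sc <- generate_tfm_scene(seed = 3)
  expect_gt(sc$truth$peak_disp_px, 0.5)
  expect_lt(sc$truth$peak_disp_px, 2)
  # the guard rejects unrecoverable amplitudes
  expect_error(generate_tfm_scene(amplitude_pa = 2000, seed = 3),
               "unrecoverable")
  # zero amplitude: deformed equals reference exactly (noise off)
  s0 <- generate_tfm_scene(amplitude_pa = 0, noise_sd = 0, seed = 3)
  expect_identical(s0$reference, s0$deformed)
})

test_that("ground-truth sidecars are written as structured text", {
  d <- withr::local_tempdir()
  sc <- generate_granule_scene(seed = 2)
  paths <- write_truth_sidecar(
    list(cell_radius_px = 50, seed = 2, granules = sc$truth),
    file.path(d, "scene"))
  expect_true(all(file.exists(paths)))
  kv <- utils::read.csv(file.path(d, "scene_truth.csv"))
  expect_true("cell_radius_px" %in% kv$key)
  tab <- utils::read.csv(file.path(d, "scene_granules.csv"))
  expect_equal(nrow(tab), nrow(sc$truth))
})
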