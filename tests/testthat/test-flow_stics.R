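test_that("stics_correlation matches the direct double-loop oracle", {
  set.seed(5)
  sub <- array(runif(8 * 8 * 10), dim = c(8, 8, 10))
  for (lag in c(0L, 1L, 2L)) {
    expect_lt(max(abs(stics_correlation(sub, lag) -
                        direct_stics_oracle(sub, lag))), 1e-10)
  }
  expect_error(stics_correlation(sub, 10), "lag")
})

test_that("lag-0 correlation peaks at zero shift; rigid translation moves it", {
  set.seed(6)
  sub <- array(runif(16 * 16 * 8), dim = c(16, 16, 8))
  m0 <- stics_correlation(sub, 0)
  pk <- which(m0 == max(m0), arr.ind = TRUE)[1, ]
  expect_equal(unname(pk), c(9, 9))       # center of a 16x16 map
  # frames translated by (2, 0) px/frame, lag 3 -> peak at (6, 0)
  base <- matrix(runif(32 * 32), 32, 32)
  st <- array(0, dim = c(32, 32, 8))
  for (f in 1:8)
    st[, , f] <- base[((seq_len(32) - 1 - 2 * (f - 1)) %% 32) + 1, ]
  m3 <- stics_correlation(st, 3)
  pk3 <- which(m3 == max(m3), arr.ind = TRUE)[1, ]
  expect_equal(unname(pk3), c(17 + 6, 17))
})

test_that("white-noise movies leave no peak above the rejection threshold", {
  set.seed(7)
  vals <- replicate(20, {
    sub <- array(rnorm(16 * 16 * 10), dim = c(16, 16, 10))
    max(stics_correlation(sub, 1)) / max(stics_correlation(sub, 0))
  })
  expect_lt(stats::median(vals), 0.2)    # below min_peak_correlation
})

test_that("uniform advection is recovered in speed and direction", {
  g <- generate_speckle_movie(size_px = 64, n_frames = 30, flow = "uniform",
                              speed_um_min = 2, direction_deg = 30,
                              seed = 42)
  mask <- cell_mask(matrix(TRUE, 64, 64), g$stack$pixel_size)
  ff <- compute_flow_field(g$stack, mask, stics_config())
  expect_lt(abs(stats::median(ff$vectors$speed) - 2) / 2, 0.10)
  ang <- atan2(ff$vectors$vy, ff$vectors$vx) * 180 / pi
  expect_lt(abs(stats::median(ang) - 30), 10)
})

test_that("static movies yield near-zero or no flow", {
  g0 <- generate_speckle_movie(size_px = 64, n_frames = 30, flow = "none",
                               seed = 42)
  mask <- cell_mask(matrix(TRUE, 64, 64), g0$stack$pixel_size)
  med0 <- tryCatch(
    stats::median(compute_flow_field(g0$stack, mask,
                                     stics_config())$vectors$speed),
    error = function(e) 0)   # "no valid flow vectors" is an acceptable null
  expect_lt(med0, 0.05 * 2)  # <= 5% of the advected-case speed
})

test_that("rotating the movie 90 degrees rotates the recovered vectors", {
  g <- generate_speckle_movie(size_px = 48, n_frames = 24, flow = "uniform",
                              speed_um_min = 2, direction_deg = 0, seed = 3)
  rot <- array(0, dim = dim(g$stack$frames))
  for (f in seq_len(dim(rot)[3])) rot[, , f] <- rot90(g$stack$frames[, , f])
  strot <- image_stack(rot, g$stack$pixel_size, g$stack$frame_interval)
  mask <- cell_mask(matrix(TRUE, 48, 48), g$stack$pixel_size)
  f1 <- compute_flow_field(g$stack, mask, stics_config())
  f2 <- compute_flow_field(strot, mask, stics_config())
  # +x flow becomes -y flow under counter-clockwise rotation (rows count
  # downward, so screen CCW maps vx -> -vy)
  expect_lt(abs(stats::median(f1$vectors$vx) -
                  -stats::median(f2$vectors$vy)) /
              abs(stats::median(f1$vectors$vx)), 0.15)
  expect_lt(abs(stats::median(f2$vectors$speed) -
                  stats::median(f1$vectors$speed)) /
              stats::median(f1$vectors$speed), 0.10)
})

test_that("doubling the advection speed doubles the recovered speed", {
  # 2 -> 4 um/min: both inside the resolvable window (a flow must displace
  # the pattern by clearly more than the PSF within the TOI to survive the
  # immobile filter) and below the aliasing guard
  mask <- cell_mask(matrix(TRUE, 64, 64), 0.1067)
  med <- vapply(c(2, 4), function(v) {
    g <- generate_speckle_movie(size_px = 64, n_frames = 30,
                                flow = "uniform", speed_um_min = v,
                                seed = 9)
    stats::median(compute_flow_field(g$stack, mask,
                                     stics_config())$vectors$speed)
  }, numeric(1))
  expect_lt(abs(med[2] / med[1] - 2) / 2, 0.10)
})

test_that("directionality and inward fraction follow the cosine definition", {
  mkfield <- function(vx, vy, x, y) {
    structure(list(vectors = data.frame(toi_index = 1, x_um = x, y_um = y,
                                        vx = vx, vy = vy,
                                        speed = sqrt(vx^2 + vy^2),
                                        directionality = NA),
                   cell_center_um = c(x = 5, y = 5),
                   config = stics_config()),
              class = "flow_field")
  }
  dir_of <- function(vx, vy, x, y) {
    tc <- c(5 - x, 5 - y)
    sum(c(vx, vy) * tc) / (sqrt(vx^2 + vy^2) * sqrt(sum(tc^2)))
  }
  # vectors pointing exactly at / away from / perpendicular to the center
  f_in <- mkfield(1, 0, 2, 5);  f_in$vectors$directionality <- dir_of(1, 0, 2, 5)
  f_out <- mkfield(-1, 0, 2, 5); f_out$vectors$directionality <- dir_of(-1, 0, 2, 5)
  f_perp <- mkfield(0, 1, 2, 5); f_perp$vectors$directionality <- dir_of(0, 1, 2, 5)
  expect_equal(inward_fraction(f_in), 1.0)
  expect_equal(inward_fraction(f_out), 0.0)
  expect_equal(inward_fraction(f_perp), 0.0)
})

test_that("radial synthetic flows produce the expected inward fractions", {
  mask <- cell_mask(matrix(TRUE, 64, 64), 0.1067)
  gin <- generate_speckle_movie(size_px = 64, n_frames = 30,
                                flow = "radial_in", speed_um_min = 1.5,
                                seed = 7)
  ff_in <- compute_flow_field(gin$stack, mask, stics_config())
  expect_gt(inward_fraction(ff_in), 0.8)
  gout <- generate_speckle_movie(size_px = 64, n_frames = 30,
                                 flow = "radial_out", speed_um_min = 1.5,
                                 seed = 7)
  expect_equal(inward_fraction(compute_flow_field(gout$stack, mask,
                                                  stics_config())), 0)
})
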