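gel <- gel_properties(1000, 0.5)

test_that("forward elasticity is linear and zero-preserving", {
  n <- 64
  tx <- matrix(0, n, n); ty <- matrix(0, n, n)
  tx[20, 20] <- 100; tx[20, 44] <- -100     # balanced dipole
  u1 <- forward_displacement(traction_field(tx, ty, 0.5), gel)
  u2 <- forward_displacement(traction_field(2 * tx, 2 * ty, 0.5), gel)
  expect_equal(u2$ux, 2 * u1$ux, tolerance = 1e-12)
  u0 <- forward_displacement(traction_field(tx * 0, ty, 0.5), gel)
  expect_true(all(u0$ux == 0) && all(u0$uy == 0))
})

test_that("point-source displacement decays like 1/r (Boussinesq)", {
  n <- 256; h <- 0.5
  tx <- matrix(0, n, n); ty <- matrix(0, n, n)
  tx[129, 129] <- 100; tx[129, 131] <- -100   # tight dipole along x
  u <- forward_displacement(traction_field(tx, ty, h), gel)
  # a dipole field decays ~ 1/r^2, so point-like monopole lobes ~ 1/r;
  # compare the single-source superposition instead: extract the response
  # to one source by symmetry -- use amplitude along y where the second
  # source contributes antisymmetrically little
  r_px <- c(10, 20, 40)
  vals <- abs(u$ux[129, 129 + r_px])
  ratio <- vals[1] / vals[3]
  # dipole: |u| ~ 1/r^2 => ratio ~ (40/10)^2 = 16 (loose band, grid effects)
  expect_gt(ratio, 8)
  expect_lt(ratio, 32)
})

test_that("FTTC round trip on a balanced ring recovers the stress field", {
  sc <- generate_tfm_scene(seed = 3, noise_sd = 0)
  rec <- solve_fttc(sc$truth$displacement, gel, lambda = 1e-4)
  num <- sum((rec$tx - sc$truth$traction$tx)^2 +
               (rec$ty - sc$truth$traction$ty)^2)
  den <- sum(sc$truth$traction$tx^2 + sc$truth$traction$ty^2)
  expect_lt(sqrt(num / den), 0.15)
  # zero-frequency suppression: recovered net force ~ 0
  expect_lt(abs(mean(rec$tx)) + abs(mean(rec$ty)), 1e-10)
  # integrated force within 15% of the ground-truth integral
  expect_lt(abs(integrate_force(rec) - sc$truth$force_nN) /
              sc$truth$force_nN, 0.15)
})

test_that("FTTC is linear and zero-preserving", {
  sc <- generate_tfm_scene(seed = 5, noise_sd = 0)
  d <- sc$truth$displacement
  t1 <- solve_fttc(d, gel, 1e-4)
  d3 <- displacement_field(3 * d$ux, 3 * d$uy, d$spacing_um)
  t3 <- solve_fttc(d3, gel, 1e-4)
  expect_equal(t3$tx, 3 * t1$tx, tolerance = 1e-9)
  z <- solve_fttc(displacement_field(d$ux * 0, d$uy * 0, d$spacing_um),
                  gel, 1e-4)
  expect_true(all(z$magnitude == 0))
  expect_error(solve_fttc(displacement_field(matrix(0, 1, 1),
                                             matrix(0, 1, 1), 1), gel),
               "degenerate")
})

test_that("Tikhonov damping is monotone in lambda on white noise", {
  set.seed(4)
  d <- displacement_field(matrix(rnorm(32 * 32, 0, 0.05), 32, 32),
                          matrix(rnorm(32 * 32, 0, 0.05), 32, 32), 1)
  mags <- vapply(c(1e-5, 1e-4, 1e-3), function(l)
    sum(solve_fttc(d, gel, l)$magnitude), numeric(1))
  expect_true(all(diff(mags) < 0))
})

test_that("round-trip error vanishes as lambda -> 0 on smooth fields", {
  sc <- generate_tfm_scene(seed = 6, noise_sd = 0)
  errs <- vapply(c(1e-2, 1e-3, 1e-4), function(l) {
    rec <- solve_fttc(sc$truth$displacement, gel, l)
    sqrt(sum((rec$tx - sc$truth$traction$tx)^2 +
               (rec$ty - sc$truth$traction$ty)^2) /
           sum(sc$truth$traction$tx^2 + sc$truth$traction$ty^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-4)
})

test_that("force integration applies the stated unit conversion", {
  # uniform 100 Pa magnitude over 100 um^2: 100 Pa * 100 um^2 = 1e4 pN = 10 nN
  tf <- traction_field(matrix(100, 10, 10), matrix(0, 10, 10),
                       spacing_um = 1)
  expect_equal(integrate_force(tf), 10)
  expect_equal(integrate_force(traction_field(matrix(0, 10, 10),
                                              matrix(0, 10, 10), 1)), 0)
  # roi restriction
  expect_equal(integrate_force(tf, roi(0, 0, 5, 10)), 5)
  expect_error(integrate_force(tf, roi(0, 0, 20, 20)), "outside")
})

test_that("template matching recovers rigid and smooth displacements", {
  set.seed(8)
  n <- 192
  ref <- synapseflow:::render_spots(n, n, runif(900, 0, n - 1),
                                    runif(900, 0, n - 1), 1.5)
  # self-match: u ~ 0 everywhere (the NCC normalisation varies with shift,
  # so the quadratic refinement carries a small sub-pixel residual)
  d0 <- estimate_displacement(ref, ref, pixel_size = 1)
  expect_lt(max(abs(c(d0$ux, d0$uy))), 0.05)
  # rigid 3-px shift down
  shifted <- rbind(matrix(0, 3, n), ref[1:(n - 3), ])
  d3 <- estimate_displacement(ref, shifted, pixel_size = 1)
  expect_lt(max(abs(d3$uy - 3)), 0.1)
  expect_lt(max(abs(d3$ux)), 0.1)
  expect_error(estimate_displacement(ref, ref[1:100, ], 1), "size")
})

test_that("smooth sub-pixel bead displacements are recovered < 0.2 px RMS", {
  sc <- generate_tfm_scene(seed = 3)
  est <- estimate_displacement(sc$reference, sc$deformed, 0.1067)
  tru <- sc$truth$displacement
  tux <- tru$ux[est$node_row_px + 1L, est$node_col_px + 1L]
  tuy <- tru$uy[est$node_row_px + 1L, est$node_col_px + 1L]
  rms_px <- sqrt(mean((est$ux - tux)^2 + (est$uy - tuy)^2)) / 0.1067
  expect_lt(rms_px, 0.2)
})

test_that("force time series behaves on identity, ramps and single frames", {
  sc <- generate_tfm_scene(seed = 9, noise_sd = 0)
  n <- nrow(sc$reference)
  # frames = reference (no deformation) -> ~0 nN
  st0 <- image_stack(array(rep(sc$reference, 2), dim = c(n, n, 2)),
                     0.1067, 15)
  fs0 <- force_timeseries(st0, sc$reference, gel)
  ramp <- generate_tfm_scene(seed = 9, noise_sd = 0)  # geometry donor
  # linear amplitude ramp: deformed_k = beads displaced by k/5 * u
  set.seed(9)
  bead_r <- runif(1100, 0, n - 1); bead_c <- runif(1100, 0, n - 1)
  tru <- ramp$truth$displacement
  interp_at <- function(m, r, c) m[cbind(pmin(round(r) + 1, n),
                                         pmin(round(c) + 1, n))]
  ref2 <- synapseflow:::render_spots(n, n, bead_r, bead_c, 1.5)
  frames <- vapply(1:5, function(k) {
    synapseflow:::render_spots(
      n, n,
      bead_r + k / 5 * interp_at(tru$uy, bead_r, bead_c) / 0.1067,
      bead_c + k / 5 * interp_at(tru$ux, bead_r, bead_c) / 0.1067, 1.5)
  }, matrix(0, n, n))
  str <- image_stack(array(frames, dim = c(n, n, 5)), 0.1067, 15)
  fsr <- force_timeseries(str, ref2, gel)
  expect_lt(fs0$force_nN[1], 0.2 * fsr$force_nN[5])
  expect_gt(stats::cor(fsr$times, fsr$force_nN, method = "spearman"), 0.95)
  expect_equal(fsr$metrics$max, max(fsr$force_nN))
  expect_equal(fsr$metrics$median, stats::median(fsr$force_nN))
  # single-frame series: all metrics equal that frame's force
  st1 <- image_stack(array(frames[, , 1], dim = c(n, n, 1)), 0.1067, 15)
  fs1 <- force_timeseries(st1, ref2, gel)
  expect_equal(fs1$metrics$max, fs1$force_nN[1])
  expect_equal(fs1$metrics$mean, fs1$force_nN[1])
  expect_equal(fs1$metrics$median, fs1$force_nN[1])
})

test_that("treatment force ratio is a nearest-sample lookup with guards", {
  fs <- structure(list(times = seq(0, 900, by = 15),
                       force_nN = seq(10, 5, length.out = 61),
                       metrics = list(max = 10, mean = 7.5, median = 7.5)),
                  class = "force_series")
  expect_equal(treatment_force_ratio(fs, 0, 900), 0.5)
  fs$force_nN <- rep(4, 61)
  expect_equal(treatment_force_ratio(fs, 100, 800), 1.0)
  expect_error(treatment_force_ratio(fs, 800, 100), "after")
  fs$force_nN[1] <- 0
  expect_error(treatment_force_ratio(fs, 0, 900), "zero")
})

test_that("recovered forces sit in the nN range for study-like parameters", {
  sc <- generate_tfm_scene(seed = 12, noise_sd = 0)
  expect_gt(sc$truth$force_nN, 0.5)
  expect_lt(sc$truth$force_nN, 100)
})
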